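# Joint Pareto scaling of training and query shifts.

# population standard deviation (1/n normalization)
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

#' Pareto-scale training and test shifts jointly
#'
#' For each column the center is the mean over the concatenation of the
#' training values and the *present* test values, and the divisor is the
#' square root of that concatenation's population standard deviation
#' (Pareto scaling).  Training and test proteins are normalized
#' simultaneously so that constant referencing offsets between data sets
#' are absorbed.
#'
#' @param train numeric matrix (no NA) with named columns.
#' @param test optional numeric matrix with the same columns; NA allowed
#'   (missing shifts are ignored in the statistics and stay NA).
#' @return list with `train`, `test` (scaled copies) and `scaling`
#'   (list with `center` and `scale`, both named by column).
#' @export
pareto_scale <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (!is.null(test)) {
    test <- as.matrix(test)
    if (!identical(colnames(train), colnames(test)))
      stop("test columns must match training columns")
  }
  center <- numeric(ncol(train)); scale <- numeric(ncol(train))
  for (j in seq_len(ncol(train))) {
    v <- c(train[, j], if (!is.null(test)) test[, j])
    s <- pop_sd(v)
    if (!is.finite(s) || s <= 0)
      stop("zero-variance shift column: ", colnames(train)[j])
    center[j] <- mean(v, na.rm = TRUE)
    scale[j] <- sqrt(s)
  }
  names(center) <- names(scale) <- colnames(train)
  out <- list(
    train = sweep(sweep(train, 2L, center), 2L, scale, "/"),
    test = if (!is.null(test))
      sweep(sweep(test, 2L, center), 2L, scale, "/"),
    scaling = list(center = center, scale = scale)
  )
  out
}

#' Apply or invert a stored scaling
#'
#' @param x numeric matrix with columns matching the scaling state.
#' @param scaling list with `center` and `scale` (from [pareto_scale()]).
#' @param invert map scaled values back to ppm.
#' @return Scaled (or unscaled) matrix.
#' @export
apply_scaling <- function(x, scaling, invert = FALSE) {
  x <- as.matrix(x)
  cols <- colnames(x)
  ctr <- scaling$center[cols]; scl <- scaling$scale[cols]
  if (anyNA(ctr) || anyNA(scl))
    stop("scaling state lacks some of the requested columns")
  if (invert) sweep(sweep(x, 2L, scl, "*"), 2L, ctr, "+")
  else sweep(sweep(x, 2L, ctr), 2L, scl, "/")
}
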