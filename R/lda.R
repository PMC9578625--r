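# The discriminant-analysis core: per-class Gaussian statistics with
# population (1/n_k) covariances, the pooled covariance
# S = (1/N) * sum_k n_k S_k, the linear scores
# f_k(x) = mu_k' S^-1 x - 1/2 mu_k' S^-1 mu_k + log(pi_k)
# with priors pi_k = n_k / N, softmax posteriors, and the quadratic
# (per-class covariance) variant.

#' Per-class mean vectors and covariance matrices
#'
#' Covariances use the population normalization 1/n_k (not n_k - 1),
#' matching the pooled-covariance definition below.
#'
#' @param values numeric matrix (N x M), complete.
#' @param labels character class labels, length N.
#' @return list with `means` (K x M, rows in alphabetical class order),
#'   `cov` (named list of M x M matrices), `counts` (named integer).
#' @export
fit_class_stats <- function(values, labels) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("training matrix contains missing values")
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(k) sum(labels == k), integer(1))
  small <- classes[counts < 2L]
  if (length(small))
    stop("class(es) with fewer than 2 training spin systems: ",
         paste(small, collapse = ", "))
  M <- ncol(values)
  means <- matrix(NA_real_, length(classes), M,
                  dimnames = list(classes, colnames(values)))
  covs <- vector("list", length(classes)); names(covs) <- classes
  for (k in classes) {
    xk <- values[labels == k, , drop = FALSE]
    mu <- colMeans(xk)
    means[k, ] <- mu
    xc <- sweep(xk, 2L, mu)
    covs[[k]] <- crossprod(xc) / nrow(xk)
  }
  list(means = means, cov = covs, counts = counts)
}

#' Pooled covariance matrix
#'
#' Class-count-weighted average of the per-class population covariances,
#' `(1/N) * sum_k n_k * S_k`, symmetrized.
#'
#' @param per_class_cov named list of M x M matrices.
#' @param class_counts named integer vector (same names).
#' @param N total count; must equal `sum(class_counts)`.
#' @return M x M matrix.
#' @export
pooled_covariance <- function(per_class_cov, class_counts,
                              N = sum(class_counts)) {
  if (sum(class_counts) != N)
    stop("class counts must sum to N")
  S <- Reduce(`+`, Map(function(C, n) n * C,
                       per_class_cov[names(class_counts)],
                       as.list(class_counts))) / N
  (S + t(S)) / 2
}

# Ensure positive definiteness: add lambda * mean(diag) * I with lambda
# escalating from 1e-6 by decades to 1e-3, then fail.
regularize_spd <- function(S, what = "covariance") {
  ok <- function(M) !inherits(try(chol(M), silent = TRUE), "try-error")
  if (ok(S)) return(structure(S, lambda = 0))
  d <- mean(diag(S))
  if (!is.finite(d) || d <= 0) d <- 1
  for (lambda in 10^seq(-6, -3)) {
    M <- S + lambda * d * diag(nrow(S))
    if (ok(M)) return(structure(M, lambda = lambda))
  }
  stop(what, " is not positive definite even after regularization")
}

#' Fit a discriminant model
#'
#' Composes [fit_class_stats()], [pooled_covariance()] and the priors
#' `pi_k = n_k / N`.  The per-class covariances are retained so the same
#' model object serves the quadratic variant.
#'
#' @param values numeric matrix (N x M) of (typically Pareto-scaled)
#'   shifts, complete.
#' @param labels residue-type labels, length N.
#' @param scaling optional scaling state (stored for reuse; queries must
#'   be scaled identically before scoring).
#' @param subset optional [shift_subset()] the columns came from.
#' @return An object of class `shiftlda_model`.
#' @export
slda_fit <- function(values, labels, scaling = NULL, subset = NULL) {
  values <- as.matrix(values)
  st <- fit_class_stats(values, labels)
  N <- sum(st$counts)
  S <- pooled_covariance(st$cov, st$counts, N)
  S <- regularize_spd(S, "pooled covariance")
  lambda <- attr(S, "lambda")
  attr(S, "lambda") <- NULL
  model <- list(
    shift_names = colnames(values),
    subset = if (!is.null(subset)) attr(as_shift_subset(subset), "subset_name"),
    classes = rownames(st$means),
    means = st$means,
    counts = st$counts,
    priors = st$counts / N,
    pooled_cov = S,
    pooled_cov_inv = chol2inv(chol(S)),
    per_class_cov = st$cov,
    regularization_lambda = lambda,
    scaling = scaling,
    N = N
  )
  class(model) <- "shiftlda_model"
  model
}

#' @export
print.shiftlda_model <- function(x, ...) {
  cat("shiftlda model: ", length(x$classes), " classes, features (",
      paste(x$shift_names, collapse = ", "), "), N = ", x$N, "\n", sep = "")
  invisible(x)
}

#' Linear discriminant scores
#'
#' Evaluates `f_k(x) = mu_k' S^-1 x - 1/2 mu_k' S^-1 mu_k + log(pi_k)`
#' for every class, with S the pooled covariance.
#'
#' @param model a `shiftlda_model`.
#' @param x numeric vector (length M) or matrix (n x M), on the model's
#'   scaled coordinates.
#' @return n x K score matrix (columns named by class).
#' @export
discriminant_score <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L,
                                   dimnames = list(NULL, model$shift_names))
       else as.matrix(x)
  if (ncol(x) != length(model$shift_names))
    stop("query has ", ncol(x), " features; model expects ",
         length(model$shift_names))
  W <- model$pooled_cov_inv %*% t(model$means)        # M x K
  b <- -0.5 * colSums(t(model$means) * W) + log(model$priors)
  scores <- x %*% W
  sweep(scores, 2L, b, "+")
}

#' Quadratic discriminant scores
#'
#' Per-class Gaussian log-density plus log prior, using each class's own
#' covariance:
#' `-1/2 log|S_k| - 1/2 (x - mu_k)' S_k^-1 (x - mu_k) + log(pi_k)`.
#'
#' @inheritParams discriminant_score
#' @return n x K score matrix.
#' @export
qda_score <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != length(model$shift_names))
    stop("query has ", ncol(x), " features; model expects ",
         length(model$shift_names))
  K <- length(model$classes)
  scores <- matrix(NA_real_, nrow(x), K,
                   dimnames = list(rownames(x), model$classes))
  for (k in model$classes) {
    Sk <- regularize_spd(model$per_class_cov[[k]],
                         paste0("covariance of class ", k))
    ch <- chol(Sk)
    logdet <- 2 * sum(log(diag(ch)))
    xc <- sweep(x, 2L, model$means[k, ])
    maha <- colSums(backsolve(ch, t(xc), transpose = TRUE)^2)
    scores[, k] <- -0.5 * logdet - 0.5 * maha + log(model$priors[[k]])
  }
  scores
}

#' Posterior class probabilities from scores
#'
#' Softmax of the per-class scores, computed stably by subtracting the
#' row maximum; rows sum to 1 and the ordering of scores is preserved.
#'
#' @param scores numeric vector or n x K matrix.
#' @return Object of the same shape with rows summing to 1.
#' @export
posterior_probabilities <- function(scores) {
  vec <- is.null(dim(scores))
  s <- if (vec) matrix(scores, nrow = 1L,
                       dimnames = list(NULL, names(scores)))
       else as.matrix(scores)
  e <- exp(s - apply(s, 1L, max))
  p <- e / rowSums(e)
  if (vec) p[1L, ] else p
}

# predicted class per row; exact ties resolved alphabetically (classes
# are stored sorted, and max.col(ties.method = "first") picks the first).
predict_class <- function(model, scores) {
  model$classes[max.col(scores, ties.method = "first")]
}
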