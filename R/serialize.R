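# Versioned JSON serialization of fitted models.

MODEL_FORMAT_VERSION <- 1L

#' Save a fitted model as JSON
#'
#' @param model a `shiftlda_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  doc <- list(
    format = "shiftlda_model",
    format_version = MODEL_FORMAT_VERSION,
    package_version = as.character(utils::packageVersion("shiftlda")),
    shift_names = model$shift_names,
    subset = model$subset,
    classes = model$classes,
    means = model$means,
    counts = as.list(model$counts),
    priors = as.list(model$priors),
    pooled_cov = model$pooled_cov,
    per_class_cov = model$per_class_cov,
    regularization_lambda = model$regularization_lambda,
    scaling = if (!is.null(model$scaling))
      list(center = as.list(model$scaling$center),
           scale = as.list(model$scaling$scale)),
    N = model$N,
    method = model$method
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON file.
#' @return A `shiftlda_model`.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "shiftlda_model"))
    stop(path, " is not a shiftlda model file")
  if (doc$format_version > MODEL_FORMAT_VERSION)
    stop("model file version ", doc$format_version,
         " is newer than this package understands")
  means <- matrix(unlist(doc$means), nrow = length(doc$classes), byrow = FALSE,
                  dimnames = list(doc$classes, doc$shift_names))
  if (is.list(doc$means))  # row-major list of rows
    means <- do.call(rbind, lapply(doc$means, unlist))
  dimnames(means) <- list(doc$classes, doc$shift_names)
  fixmat <- function(m) {
    m <- if (is.list(m)) do.call(rbind, lapply(m, unlist)) else as.matrix(m)
    dimnames(m) <- list(doc$shift_names, doc$shift_names)
    m
  }
  S <- fixmat(doc$pooled_cov)
  model <- list(
    shift_names = doc$shift_names,
    subset = doc$subset,
    classes = doc$classes,
    means = means,
    counts = unlist(doc$counts)[doc$classes],
    priors = unlist(doc$priors)[doc$classes],
    pooled_cov = S,
    pooled_cov_inv = chol2inv(chol(regularize_spd(S))),
    per_class_cov = lapply(doc$per_class_cov[doc$classes], fixmat),
    regularization_lambda = doc$regularization_lambda,
    scaling = if (!is.null(doc$scaling))
      list(center = unlist(doc$scaling$center)[doc$shift_names],
           scale = unlist(doc$scaling$scale)[doc$shift_names]),
    N = doc$N,
    method = doc$method
  )
  class(model) <- "shiftlda_model"
  model
}
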