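# Evaluation protocols: protein-level leave-one-out cross-validation,
# row-normalized confusion charts, permutation feature importance.

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Protein-level leave-one-out cross-validation
#'
#' Holds out one protein at a time, trains on the spin systems of all
#' other proteins (restricted to the residue types present in the
#' held-out protein), Pareto-scales training and test jointly, and
#' classifies the held-out spin systems.  Two eligibility modes:
#' `"restricted"` scores every spin system with at least one subset
#' shift, routing incomplete ones through restricted models;
#' `"complete"` scores only spin systems complete for the subset, where
#' glycine (no CB/HB) and proline (no HN) count as complete when all
#' their structurally possible shifts are present.
#'
#' @param proteins named list of `spin_table`s (names = protein ids), or
#'   a single `spin_table` split by its `source` column.
#' @param subset shift subset.
#' @param mode `"restricted"` or `"complete"` (see above).
#' @param method `"lda"` or `"qda"`.
#' @return Object of class `shiftlda_loo`: list with `per_protein`
#'   (data.frame protein, n, accuracy), `weighted_mean_accuracy`,
#'   `truth`/`predicted` label vectors (for confusion charts), `mode`,
#'   `subset`.
#' @export
leave_one_out <- function(proteins, subset = "iii",
                          mode = c("restricted", "complete"),
                          method = c("lda", "qda")) {
  mode <- match.arg(mode); method <- match.arg(method)
  subset <- as_shift_subset(subset)
  if (inherits(proteins, "spin_table")) {
    if (all(is.na(proteins$source)))
      stop("a single spin_table needs a `source` column to split proteins")
    proteins <- split(as.data.frame(proteins), proteins$source)
    proteins <- lapply(proteins, as_spin_table, warn = FALSE)
  }
  if (length(proteins) < 2L) stop("leave-one-out needs at least 2 proteins")
  if (is.null(names(proteins)))
    names(proteins) <- paste0("protein", seq_along(proteins))
  res <- data.frame(protein = character(0), n = integer(0),
                    accuracy = numeric(0), stringsAsFactors = FALSE)
  truth_all <- character(0); pred_all <- character(0)
  for (p in names(proteins)) {
    test <- proteins[[p]]
    train <- do.call(rbind, lapply(proteins[names(proteins) != p],
                                   as.data.frame))
    train <- as_spin_table(train, warn = FALSE)
    eligible <- if (mode == "complete")
      is_complete(test, subset, respect_structure = TRUE)
    else shift_pattern(test, subset) != ""
    eligible <- eligible & !is.na(test$residue_type)
    if (!any(eligible)) {
      warning("protein ", p, ": no classifiable spin systems; excluded",
              call. = FALSE)
      next
    }
    test <- as_spin_table(as.data.frame(test)[eligible, , drop = FALSE],
                          warn = FALSE)
    allowed <- sort(unique(test$residue_type))
    cl <- classify_spins(test, train, subset, allowed_types = allowed,
                         method = method)
    acc <- mean(cl$table$predicted == test$residue_type)
    res <- rbind(res, data.frame(protein = p, n = nrow(test), accuracy = acc,
                                 stringsAsFactors = FALSE))
    truth_all <- c(truth_all, test$residue_type)
    pred_all <- c(pred_all, cl$table$predicted)
  }
  out <- list(
    per_protein = res,
    weighted_mean_accuracy = sum(res$accuracy * res$n) / sum(res$n),
    truth = truth_all,
    predicted = pred_all,
    mode = mode,
    subset = attr(subset, "subset_name")
  )
  class(out) <- "shiftlda_loo"
  out
}

#' @export
print.shiftlda_loo <- function(x, ...) {
  cat("leave-one-out over ", nrow(x$per_protein), " proteins (subset ",
      x$subset, ", ", x$mode, " mode)\n", sep = "")
  print(x$per_protein, row.names = FALSE)
  cat(sprintf("weighted mean accuracy: %.2f%%\n",
              100 * x$weighted_mean_accuracy))
  invisible(x)
}

#' Row-normalized confusion chart
#'
#' Aggregates (true, predicted) label pairs into counts and normalizes
#' each row, so row k shows how spin systems of true type k were
#' distributed over predicted types; the diagonal is the per-type
#' sensitivity.
#'
#' @param true_types,predicted_types equal-length label vectors.
#' @param classes class order (default: alphabetical union).
#' @return Object of class `shiftlda_confusion`: list with `matrix`
#'   (row-normalized), `counts`, `row_counts`, `classes`.
#' @export
confusion_chart <- function(true_types, predicted_types, classes = NULL) {
  if (length(true_types) != length(predicted_types))
    stop("label vectors must have equal length")
  if (is.null(classes))
    classes <- sort(unique(c(true_types, predicted_types)))
  counts <- table(factor(true_types, levels = classes),
                  factor(predicted_types, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(true = classes, predicted = classes))
  row_counts <- rowSums(counts)
  mat <- counts / ifelse(row_counts == 0, 1, row_counts)
  out <- list(matrix = mat, counts = counts, row_counts = row_counts,
              classes = classes)
  class(out) <- "shiftlda_confusion"
  out
}

#' @export
print.shiftlda_confusion <- function(x, digits = 2, ...) {
  cat("confusion chart (rows = true type, row-normalized)\n")
  print(round(x$matrix, digits))
  invisible(x)
}

#' Permutation importance of each chemical shift
#'
#' Trains once on the intact (Pareto-scaled) training table.  Then, for
#' each shift column and each repeat, shuffles that column alone in a
#' copy of the table, classifies every row with the intact model, and
#' records the error rate (1 - accuracy).  Shuffling a column destroys
#' its association with residue type while preserving its marginal
#' distribution, so the error increase measures how much the classifier
#' relies on that shift.
#'
#' @param training a `spin_table` with residue types.
#' @param subset shift subset; rows must be complete for it (incomplete
#'   rows are dropped).
#' @param n_repeats shuffles per column (1000 for publication-grade
#'   error bars; reduce for quick checks).
#' @param seed RNG seed; results are bit-reproducible given the seed.
#' @return Object of class `shiftlda_importance`: `summary` data.frame
#'   (shift, mean_error, sd_error), `baseline_error`, `n_repeats`,
#'   `seed`.
#' @export
permutation_importance <- function(training, subset = "iii",
                                   n_repeats = 1000L, seed = 1L) {
  subset <- as_shift_subset(subset)
  keep <- is_complete(training, subset) & !is.na(training$residue_type)
  tab <- as.data.frame(training)[keep, , drop = FALSE]
  if (!nrow(tab)) stop("no training rows complete for the subset")
  X <- as.matrix(tab[, as.character(subset), drop = FALSE])
  labels <- tab$residue_type
  sc <- pareto_scale(X)
  model <- slda_fit(sc$train, labels, scaling = sc$scaling, subset = subset)
  base_pred <- predict_class(model, discriminant_score(model, sc$train))
  baseline <- mean(base_pred != labels)
  M <- length(subset)
  err <- matrix(NA_real_, n_repeats, M, dimnames = list(NULL, subset))
  with_seed(seed, {
    for (j in seq_len(M)) {
      for (r in seq_len(n_repeats)) {
        Xs <- sc$train
        Xs[, j] <- Xs[sample.int(nrow(Xs)), j]
        pred <- predict_class(model, discriminant_score(model, Xs))
        err[r, j] <- mean(pred != labels)
      }
    }
  })
  out <- list(
    summary = data.frame(
      shift = as.character(subset),
      mean_error = colMeans(err),
      sd_error = apply(err, 2L, stats::sd),
      stringsAsFactors = FALSE
    ),
    baseline_error = baseline,
    n_repeats = n_repeats,
    seed = seed
  )
  class(out) <- "shiftlda_importance"
  out
}

#' @export
print.shiftlda_importance <- function(x, ...) {
  cat("permutation importance (", x$n_repeats, " shuffles per shift, ",
      "baseline error ", sprintf("%.4f", x$baseline_error), ")\n", sep = "")
  s <- x$summary[order(-x$summary$mean_error), ]
  print(s, row.names = FALSE)
  invisible(x)
}
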