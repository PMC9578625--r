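# Classifying spin systems, including incomplete ones through
# restricted models (fresh model on the query's present shifts, trained
# on spin systems that have all of them).

# training rows usable for a column set: all columns present, residue
# type known and allowed
restricted_training <- function(training, cols, allowed_types) {
  m <- shift_matrix(training, cols)
  ok <- rowSums(is.na(m)) == 0L &
    !is.na(training$residue_type) &
    training$residue_type %in% allowed_types
  list(values = m[ok, , drop = FALSE],
       labels = training$residue_type[ok])
}

#' Fit a restricted model for a missingness pattern
#'
#' Trains a fresh model on only the shift columns in `present_shifts`,
#' using the training spin systems that have all of them and whose
#' residue type is in `allowed_types`.  Pareto scaling is recomputed
#' jointly on the restricted table plus the query rows.
#'
#' @param training a `spin_table` with residue types.
#' @param present_shifts character vector of shift names (subset of the
#'   seven canonical names).
#' @param allowed_types residue types the model may predict (the types
#'   present in the target protein).
#' @param query optional numeric matrix of query rows (columns =
#'   `present_shifts`) included in the joint scaling.
#' @param method `"lda"` or `"qda"`.
#' @return list with `model` (a `shiftlda_model`) and `query_scaled`.
#' @export
fit_restricted <- function(training, present_shifts, allowed_types,
                           query = NULL, method = c("lda", "qda")) {
  method <- match.arg(method)
  present_shifts <- as.character(present_shifts)
  if (!length(present_shifts) ||
      !all(present_shifts %in% canonical_shifts()))
    stop("no usable shifts in query")
  # classes whose structure forbids one of the present shifts (a spin
  # system showing CB or HB cannot be glycine; one showing HN cannot be
  # proline) are dropped from the restricted model rather than trained
  impossible <- names(STRUCTURAL_ABSENT)[vapply(STRUCTURAL_ABSENT,
    function(a) any(a %in% present_shifts), logical(1))]
  allowed_types <- setdiff(sort(allowed_types), impossible)
  if (!length(allowed_types))
    stop("no structurally possible residue type for shifts (",
         paste(present_shifts, collapse = ", "), ")")
  tr <- restricted_training(training, present_shifts, allowed_types)
  have <- sort(unique(tr$labels))
  missing_classes <- setdiff(allowed_types, have)
  if (length(missing_classes))
    stop("no complete training spin systems for class(es): ",
         paste(missing_classes, collapse = ", "),
         " on shifts (", paste(present_shifts, collapse = ", "), ")")
  sc <- pareto_scale(tr$values, query)
  model <- slda_fit(sc$train, tr$labels, scaling = sc$scaling)
  model$method <- method
  list(model = model, query_scaled = sc$test)
}

#' Classify spin systems
#'
#' For each distinct missingness pattern among the queries, a restricted
#' model is fit on the training spin systems complete for that pattern
#' (classes limited to `allowed_types`), training and queries are
#' Pareto-scaled jointly, and each query receives per-class scores,
#' softmax posteriors and a predicted type (ties broken alphabetically).
#' Queries with no usable shift raise an error.
#'
#' @param queries a `spin_table` of unassigned spin systems.
#' @param training a `spin_table` with residue types.
#' @param subset shift subset to use (name or [shift_subset()]).
#' @param allowed_types residue types present in the target protein
#'   (default: all types in the training data).
#' @param method `"lda"` (pooled covariance) or `"qda"` (per-class).
#' @param exclusions optional named list: query id -> residue types whose
#'   posterior is zeroed (structural exclusions) before renormalization.
#' @return Object of class `shiftlda_classification`: list with
#'   `table` (data.frame id, predicted, posterior, shifts_used),
#'   `scores` and `posteriors` (n x K matrices), `classes`, `subset`.
#' @export
classify_spins <- function(queries, training, subset = "iii",
                           allowed_types = NULL,
                           method = c("lda", "qda"),
                           exclusions = NULL) {
  method <- match.arg(method)
  subset <- as_shift_subset(subset)
  if (is.null(allowed_types))
    allowed_types <- sort(unique(stats::na.omit(training$residue_type)))
  allowed_types <- sort(unique(allowed_types))
  qm <- shift_matrix(queries, subset)
  patterns <- shift_pattern(queries, subset)
  if (any(patterns == ""))
    stop("spin system(s) with no usable shift in subset: ",
         paste(queries$id[patterns == ""], collapse = ", "))
  n <- nrow(qm); K <- length(allowed_types)
  scores <- matrix(NA_real_, n, K, dimnames = list(queries$id, allowed_types))
  for (pat in unique(patterns)) {
    cols <- strsplit(pat, ",")[[1]]
    rows <- which(patterns == pat)
    fr <- fit_restricted(training, cols, allowed_types,
                         query = qm[rows, cols, drop = FALSE], method = method)
    sc <- if (method == "qda") qda_score(fr$model, fr$query_scaled)
          else discriminant_score(fr$model, fr$query_scaled)
    scores[rows, colnames(sc)] <- sc
  }
  # classes absent from a row's restricted model (structurally
  # impossible for its shift pattern) get probability zero
  scores[is.na(scores)] <- -Inf
  post <- posterior_probabilities(scores)
  if (!is.null(exclusions)) {
    for (qid in intersect(names(exclusions), rownames(post))) {
      drop <- intersect(exclusions[[qid]], colnames(post))
      if (!length(drop)) next
      post[qid, drop] <- 0
      tot <- sum(post[qid, ])
      if (tot > 0) post[qid, ] <- post[qid, ] / tot
      scores[qid, drop] <- -Inf
    }
  }
  predicted <- allowed_types[max.col(post, ties.method = "first")]
  out <- list(
    table = data.frame(
      id = queries$id,
      predicted = predicted,
      posterior = post[cbind(seq_len(n), match(predicted, allowed_types))],
      shifts_used = patterns,
      stringsAsFactors = FALSE
    ),
    scores = scores,
    posteriors = post,
    classes = allowed_types,
    subset = attr(subset, "subset_name"),
    method = method
  )
  class(out) <- "shiftlda_classification"
  out
}

#' @export
print.shiftlda_classification <- function(x, ...) {
  cat("shiftlda classification of ", nrow(x$table), " spin system(s), ",
      length(x$classes), " classes (", x$method, ", subset ",
      x$subset, ")\n", sep = "")
  print(utils::head(x$table, 10L))
  if (nrow(x$table) > 10L) cat("...\n")
  invisible(x)
}
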