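# Application 2: transferring assignments from a reference (e.g. BMRB)
# peak list to an experimental peak list, combining peak proximity with
# class consistency of the preceding residue as judged by the
# classifier.

# preceding residue type from a reference label like "Y39-V40"
# (residue-pair convention: first residue = preceding).  Returns NA
# when the label does not parse.
preceding_type_from_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Z])[0-9]+[-]", label))[[1]]
  if (length(m) == 2L && m[2L] %in% aa_alphabet()) m[2L] else NA_character_
}

#' Transfer assignments between two 2D peak lists
#'
#' Each labeled reference peak (label convention `X##-Y##`, the first
#' residue being the preceding one, e.g. `Y39-V40` precedes with
#' tyrosine) is matched against experimental peaks within a per-axis
#' search window.  Candidates are ranked lexicographically by
#' (class-consistency, posterior of the reference's preceding type,
#' -distance), where an experimental peak is class-consistent when its
#' predicted preceding-residue type equals the reference's.  Assignments
#' are resolved greedily one-to-one in order of decreasing best-candidate
#' margin; a match is flagged ambiguous when two or more class-consistent
#' candidates exist (the dashed-arrow situation).
#'
#' @param reference `peak_list` with residue-pair labels.
#' @param experimental `peak_list`; row i corresponds to row i of
#'   `posteriors` (or of `experimental_spins`).
#' @param posteriors matrix (rows = experimental peaks, columns =
#'   residue types) of preceding-residue posteriors, e.g.
#'   `classify_spins(...)$posteriors`.  Alternatively supply
#'   `experimental_spins` + `training` and it is computed here.
#' @param experimental_spins optional `spin_table` of the preceding
#'   residues' shifts (typically subset "ii"), one row per experimental
#'   peak, in peak order.
#' @param training optional training `spin_table` (used with
#'   `experimental_spins`).
#' @param subset shift subset for the internal classification.
#' @param radius per-axis search window in ppm, `c(h = , n = )`.
#' @param axis_scale per-axis divisors in ppm balancing H and N
#'   dispersion in the distance, `c(h = , n = )`.
#' @return Object of class `shiftlda_transfer`: `matches` data.frame
#'   (one row per reference peak: ref_label, ref_n, ref_h,
#'   preceding_type, exp_peak, exp_n, exp_h, distance, class_consistent,
#'   lda_probability, ambiguous, assigned) and `candidates` (the full
#'   ranked candidate table).
#' @export
transfer_assignments <- function(reference, experimental,
                                 posteriors = NULL,
                                 experimental_spins = NULL,
                                 training = NULL, subset = "ii",
                                 radius = c(h = 0.1, n = 0.5),
                                 axis_scale = c(h = 1.0, n = 5.0)) {
  if (is.null(posteriors)) {
    if (is.null(experimental_spins) || is.null(training))
      stop("supply `posteriors`, or `experimental_spins` plus `training`")
    cl <- classify_spins(experimental_spins, training, subset)
    posteriors <- cl$posteriors
  }
  posteriors <- as.matrix(posteriors)
  if (nrow(posteriors) != nrow(experimental))
    stop("posterior rows must match experimental peaks")
  pred <- colnames(posteriors)[max.col(posteriors, ties.method = "first")]

  pre_type <- vapply(reference$label, function(l)
    if (is.na(l)) NA_character_ else preceding_type_from_label(l),
    character(1), USE.NAMES = FALSE)
  skip <- is.na(pre_type)
  if (any(skip & !is.na(reference$label)))
    warning("skipping reference peak(s) with unparsable label: ",
            paste(stats::na.omit(reference$label[skip]), collapse = ", "),
            call. = FALSE)

  cand_all <- list()
  per_ref <- vector("list", nrow(reference))
  for (i in which(!skip)) {
    dh <- experimental$h_ppm - reference$h_ppm[i]
    dn <- experimental$n_ppm - reference$n_ppm[i]
    inwin <- which(abs(dh) <= radius[["h"]] & abs(dn) <= radius[["n"]])
    if (!length(inwin)) { per_ref[i] <- list(NULL); next }
    dist <- sqrt((dh[inwin] / axis_scale[["h"]])^2 +
                 (dn[inwin] / axis_scale[["n"]])^2)
    type <- pre_type[i]
    prob <- if (type %in% colnames(posteriors)) posteriors[inwin, type]
            else rep(0, length(inwin))
    cons <- pred[inwin] == type
    ord <- order(-cons, -prob, dist)
    cand <- data.frame(
      ref = i, ref_label = reference$label[i], preceding_type = type,
      exp_peak = inwin[ord],
      distance = dist[ord],
      class_consistent = cons[ord],
      lda_probability = unname(prob[ord]),
      rank = seq_along(ord),
      stringsAsFactors = FALSE
    )
    per_ref[[i]] <- cand
    cand_all[[length(cand_all) + 1L]] <- cand
  }

  # greedy one-to-one resolution, most clear-cut reference first:
  # margin = posterior gap between the two best class-consistent
  # candidates (Inf when at most one is consistent).
  margin <- vapply(seq_len(nrow(reference)), function(i) {
    cand <- per_ref[[i]]
    if (is.null(cand)) return(-Inf)
    p <- cand$lda_probability[cand$class_consistent]
    if (length(p) >= 2L) p[1L] - p[2L] else Inf
  }, numeric(1))
  taken <- logical(nrow(experimental))
  rows <- list()
  for (i in order(-margin)) {
    cand <- per_ref[[i]]
    base <- data.frame(
      ref = i,
      ref_label = reference$label[i],
      ref_n = reference$n_ppm[i], ref_h = reference$h_ppm[i],
      preceding_type = pre_type[i],
      exp_peak = NA_integer_, exp_n = NA_real_, exp_h = NA_real_,
      distance = NA_real_, class_consistent = NA,
      lda_probability = NA_real_, ambiguous = NA, assigned = FALSE,
      stringsAsFactors = FALSE
    )
    if (!skip[i] && !is.null(cand)) {
      avail <- cand[!taken[cand$exp_peak], , drop = FALSE]
      base$ambiguous <- sum(cand$class_consistent) >= 2L
      if (nrow(avail)) {
        top <- avail[1L, ]
        base$exp_peak <- top$exp_peak
        base$exp_n <- experimental$n_ppm[top$exp_peak]
        base$exp_h <- experimental$h_ppm[top$exp_peak]
        base$distance <- top$distance
        base$class_consistent <- top$class_consistent
        base$lda_probability <- top$lda_probability
        base$assigned <- TRUE
        taken[top$exp_peak] <- TRUE
      }
    }
    rows[[length(rows) + 1L]] <- base
  }
  matches <- do.call(rbind, rows)
  matches <- matches[order(matches$ref), , drop = FALSE]
  rownames(matches) <- NULL
  out <- list(
    matches = matches,
    candidates = if (length(cand_all)) do.call(rbind, cand_all)
                 else data.frame(),
    radius = radius, axis_scale = axis_scale
  )
  class(out) <- "shiftlda_transfer"
  out
}

#' @export
print.shiftlda_transfer <- function(x, ...) {
  cat("assignment transfer: ", sum(x$matches$assigned), " of ",
      nrow(x$matches), " reference peaks assigned\n", sep = "")
  print(x$matches, row.names = FALSE)
  invisible(x)
}
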