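# Application 1: mapping spin-system chains onto the protein sequence.
# Candidate amino-acid sequences are enumerated from per-position class
# posteriors and filtered against the sequence ("impossible" chains are
# discarded but kept in the report).

#' Define a spin-system chain
#'
#' An ordered run of sequentially linked spin systems, N- to C-terminal
#' (index 1 = most N-terminal member).  The optional `pre` spin system
#' is the residue immediately preceding the chain, for which usually
#' only part of the shifts is known; when present, candidate sequences
#' have length `length(members) + 1` and start with the pre residue.
#'
#' @param id chain identifier.
#' @param members character ids of the member spin systems (N to C).
#' @param pre optional id of the preceding residue's spin system.
#' @return Object of class `ss_chain`.
#' @export
ss_chain <- function(id, members, pre = NULL) {
  members <- as.character(members)
  if (!length(members)) stop("chain needs at least one member")
  structure(list(id = as.character(id), members = members,
                 pre = if (!is.null(pre) && !is.na(pre) && nzchar(pre))
                   as.character(pre)),
            class = "ss_chain")
}

#' @export
print.ss_chain <- function(x, ...) {
  cat("chain ", x$id, ": ",
      if (!is.null(x$pre)) paste0("[pre ", x$pre, "] "),
      paste(x$members, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Read chains from a TSV/CSV file
#'
#' Columns: `chain_id`, optional `pre_id` (empty = none), `members`
#' (comma-separated spin-system ids, N- to C-terminal).
#'
#' @param path file path.
#' @return list of [ss_chain()].
#' @export
parse_chain_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!all(c("chain_id", "members") %in% names(df)))
    stop("chain table needs columns chain_id, members (and optional pre_id)")
  lapply(seq_len(nrow(df)), function(i) {
    ss_chain(df$chain_id[i],
             strsplit(df$members[i], ",")[[1]],
             pre = if ("pre_id" %in% names(df)) df$pre_id[i])
  })
}

# posteriors for the chain's positions (pre first when present):
# rows = positions, cols = classes
chain_posteriors <- function(chain, classification) {
  ids <- c(chain$pre, chain$members)
  miss <- setdiff(ids, rownames(classification$posteriors))
  if (length(miss))
    stop("chain ", chain$id, ": spin system(s) not classified: ",
         paste(miss, collapse = ", "))
  classification$posteriors[ids, , drop = FALSE]
}

#' Enumerate candidate sequences for a chain
#'
#' At each chain position the residue types with posterior >=
#' `inclusion_threshold` are retained (at most `top_k`, by decreasing
#' posterior); if none passes, the single best type is kept with a
#' warning.  Candidates are the Cartesian product over positions; each
#' candidate's joint probability is the product of its per-position
#' posteriors.  Output is sorted by decreasing joint probability and
#' capped at `max_candidates` (with a warning when the cap bites).
#'
#' @param chain an [ss_chain()].
#' @param classification a `shiftlda_classification` covering the
#'   chain's spin systems (see [classify_spins()]).
#' @param inclusion_threshold posterior below which a type is not
#'   considered "probable" (default 0.01).
#' @param top_k per-position cap on retained types (default 5; use `Inf`
#'   for the full distribution).
#' @param max_candidates hard cap on enumerated candidates.
#' @return data.frame (class `chain_candidates`) with columns `sequence`
#'   and `joint_probability`, sorted by decreasing probability.
#' @export
enumerate_candidates <- function(chain, classification,
                                 inclusion_threshold = 0.01, top_k = 5,
                                 max_candidates = 10000L) {
  post <- chain_posteriors(chain, classification)
  classes <- colnames(post)
  kept <- vector("list", nrow(post))
  for (i in seq_len(nrow(post))) {
    p <- post[i, ]
    ord <- order(-p, classes)          # probability desc, alphabetical ties
    sel <- ord[p[ord] >= inclusion_threshold]
    if (length(sel) > top_k) sel <- sel[seq_len(top_k)]
    if (!length(sel)) {
      warning("chain ", chain$id, ", position ", i,
              ": no type above threshold; keeping the single best type",
              call. = FALSE)
      sel <- ord[1L]
    }
    kept[[i]] <- stats::setNames(p[sel], classes[sel])
  }
  n_comb <- prod(vapply(kept, length, numeric(1)))
  grid <- expand.grid(lapply(kept, names), stringsAsFactors = FALSE)
  probs <- Reduce(`*`, lapply(seq_along(kept), function(i)
    kept[[i]][grid[[i]]]))
  seqs <- do.call(paste0, grid)
  ord <- order(-probs, seqs)
  if (n_comb > max_candidates) {
    warning("chain ", chain$id, ": candidate cap hit (", n_comb, " > ",
            max_candidates, "); keeping the ", max_candidates,
            " most probable", call. = FALSE)
    ord <- ord[seq_len(max_candidates)]
  }
  out <- data.frame(sequence = seqs[ord],
                    joint_probability = unname(probs[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "chain_id") <- chain$id
  attr(out, "has_pre") <- !is.null(chain$pre)
  class(out) <- c("chain_candidates", class(out))
  out
}

# all (overlapping) 1-based start positions of `pattern` in `seq`
substring_positions <- function(pattern, seq) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Filter chain candidates against the protein sequence
#'
#' Annotates each candidate with every (possibly overlapping) 1-based
#' start position where it occurs in the protein sequence.  Candidates
#' that occur nowhere are marked `discarded` but kept in the report.
#' Probabilities are never altered by filtering.
#'
#' @param candidates a `chain_candidates` data.frame.
#' @param sequence a [protein_seq()].
#' @return The candidates with `positions` (comma-joined starts, "" when
#'   none), `n_positions` and `discarded` columns added.
#' @export
filter_by_sequence <- function(candidates, sequence) {
  pos <- lapply(candidates$sequence, substring_positions, seq = sequence$seq)
  candidates$positions <- vapply(pos, paste, character(1), collapse = ",")
  candidates$n_positions <- lengths(pos)
  candidates$discarded <- candidates$n_positions == 0L
  candidates
}

#' Map a chain onto the protein sequence
#'
#' Composes [enumerate_candidates()] and [filter_by_sequence()].  A
#' chain is unambiguously mapped when exactly one surviving candidate
#' has exactly one sequence position.  An empty survivor set is a valid,
#' reported outcome (the classifier excluded the true type somewhere;
#' manual intervention is needed).
#'
#' @inheritParams enumerate_candidates
#' @param sequence a [protein_seq()].
#' @return data.frame report (class `chain_mapping`): `chain_id`,
#'   `candidate_sequence`, `joint_probability`, `positions`,
#'   `discarded`; attributes `unambiguous`, `n_survivors`,
#'   `best_position` (start of the unique mapping when unambiguous; the
#'   candidate starts at the `pre` residue when the chain has one) and
#'   `member_start` (position of the first chain member).
#' @export
map_chain <- function(chain, classification, sequence,
                      inclusion_threshold = 0.01, top_k = 5,
                      max_candidates = 10000L) {
  cand <- enumerate_candidates(chain, classification,
                               inclusion_threshold, top_k, max_candidates)
  cand <- filter_by_sequence(cand, sequence)
  report <- data.frame(
    chain_id = chain$id,
    candidate_sequence = cand$sequence,
    joint_probability = cand$joint_probability,
    positions = cand$positions,
    discarded = cand$discarded,
    stringsAsFactors = FALSE
  )
  surv <- report[!report$discarded, , drop = FALSE]
  unamb <- nrow(surv) == 1L && surv$positions[1L] != "" &&
    !grepl(",", surv$positions[1L])
  attr(report, "n_survivors") <- nrow(surv)
  attr(report, "unambiguous") <- unamb
  attr(report, "best_position") <- if (unamb) as.integer(surv$positions[1L])
  # position of the first chain member (candidates start at `pre`)
  attr(report, "member_start") <- if (unamb)
    as.integer(surv$positions[1L]) + as.integer(!is.null(chain$pre))
  class(report) <- c("chain_mapping", class(report))
  report
}

# CB windows (ppm) for "manual" coarse typing; ranges chosen wide enough
# to cover disordered-protein CB distributions without overlap.
MANUAL_CB_WINDOWS <- list(A = c(15, 23), S = c(60, 66.5), T = c(66.5, 73))

#' Coarse manual residue typing of a chain
#'
#' The traditional baseline against which the classifier is compared:
#' glycine from the structural absence of CB and HB (with CA present),
#' alanine/serine/threonine from their characteristic CB windows, and
#' `X` for everything else.
#'
#' @param chain an [ss_chain()].
#' @param spins a `spin_table` containing the chain's spin systems.
#' @return Character vector of coarse types (pre first when present).
#' @export
manual_baseline <- function(chain, spins) {
  ids <- c(chain$pre, chain$members)
  idx <- match(ids, spins$id)
  if (anyNA(idx))
    stop("chain ", chain$id, ": spin system(s) missing from table: ",
         paste(ids[is.na(idx)], collapse = ", "))
  vapply(idx, function(i) {
    ca <- spins$CA[i]; cb <- spins$CB[i]; hb <- spins$HB[i]
    if (!is.na(ca) && is.na(cb) && is.na(hb)) return("G")
    if (!is.na(cb)) {
      for (t in names(MANUAL_CB_WINDOWS)) {
        w <- MANUAL_CB_WINDOWS[[t]]
        if (cb >= w[1L] && cb < w[2L]) return(t)
      }
    }
    "X"
  }, character(1))
}

#' Residue types excluded by covalent structure
#'
#' Rules usable before any statistics: the presence of a CB or HB shift
#' (including raw HB2/HB3) excludes glycine; two distinct HB shifts
#' exclude alanine, isoleucine, threonine and valine, whose beta protons
#' are chemically equivalent.  The result can be passed to
#' [classify_spins()] as `exclusions` to zero those classes' posteriors.
#'
#' @param spins a `spin_table` (raw HB2/HB3 columns are used if
#'   present).
#' @param tol minimum ppm difference for HB2/HB3 to count as distinct.
#' @return Named list: spin-system id -> excluded residue types
#'   (possibly empty).
#' @export
structural_exclusions <- function(spins, tol = 0.0) {
  df <- as.data.frame(spins)
  hb2 <- if ("HB2" %in% names(df)) df$HB2 else rep(NA_real_, nrow(df))
  hb3 <- if ("HB3" %in% names(df)) df$HB3 else rep(NA_real_, nrow(df))
  out <- lapply(seq_len(nrow(df)), function(i) {
    ex <- character(0)
    if (!is.na(df$CB[i]) || !is.na(df$HB[i]) ||
        !is.na(hb2[i]) || !is.na(hb3[i]))
      ex <- "G"
    if (!is.na(hb2[i]) && !is.na(hb3[i]) && abs(hb2[i] - hb3[i]) > tol)
      ex <- c(ex, "A", "I", "T", "V")
    ex
  })
  stats::setNames(out, df$id)
}
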