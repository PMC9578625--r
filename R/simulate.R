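# Synthetic fixtures: class-conditional Gaussian spin systems with the
# missingness structure of real data (Gly lacks CB/HB, Pro lacks HN),
# plus chains and jittered peak lists.  Default means are plausible
# random-coil-like values shipped as clearly-labeled synthetic data;
# they are fixtures, not database statistics.

#' Default synthetic class model
#'
#' Loads the synthetic per-residue shift means, diagonal standard
#' deviations and class frequencies from
#' `extdata/synthetic_class_model.tsv`.
#'
#' @param sd optional named per-shift standard deviations overriding the
#'   defaults (ppm).
#' @return Object of class `class_model`: list with `classes`, `means`
#'   (20 x 7, NA at structurally absent shifts), `sds` (same shape),
#'   `freqs` (sums to 1).
#' @export
default_class_model <- function(sd = NULL) {
  path <- system.file("extdata", "synthetic_class_model.tsv",
                      package = "shiftlda", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  means <- as.matrix(df[, canonical_shifts()])
  rownames(means) <- df$residue
  base_sd <- c(HN = 0.25, N = 2.5, CO = 0.7, CA = 0.7, CB = 0.8,
               HA = 0.15, HB = 0.20)
  if (!is.null(sd)) base_sd[names(sd)] <- sd
  sds <- matrix(rep(base_sd[canonical_shifts()], each = nrow(means)),
                nrow(means), dimnames = dimnames(means))
  sds[is.na(means)] <- NA_real_
  class_model(df$residue, means, sds, stats::setNames(df$freq, df$residue))
}

#' Build a synthetic class model
#'
#' @param classes residue types.
#' @param means K x 7 matrix of shift means (ppm; NA = structurally
#'   absent).
#' @param sds K x 7 matrix of per-shift standard deviations (> 0 where
#'   the mean is defined; diagonal covariances).
#' @param freqs class frequencies (normalized to sum to 1).
#' @return A `class_model`.
#' @export
class_model <- function(classes, means, sds, freqs) {
  if (any(sds[!is.na(means)] <= 0, na.rm = TRUE))
    stop("all standard deviations must be positive")
  freqs <- freqs / sum(freqs)
  structure(list(classes = classes, means = means, sds = sds,
                 freqs = freqs),
            class = "class_model")
}

#' Simulate a protein and its spin systems
#'
#' Draws a residue sequence from the model's class frequencies and, for
#' every residue, a spin system from the class-conditional Gaussian.
#' Structural missingness is applied (glycine CB/HB, proline HN), and an
#' optional extra fraction of the remaining shifts is removed completely
#' at random.
#'
#' @param model a `class_model`.
#' @param length number of residues.
#' @param seed RNG seed (generation is a pure function of parameters and
#'   seed).
#' @param missing_rate extra random missingness fraction in `[0, 1)`.
#' @param id protein identifier (used in ids and `source`).
#' @return list with `sequence` (a [protein_seq()]) and `spins` (a
#'   `spin_table` with true `residue_type` and `sequence_position`).
#' @export
sample_protein <- function(model, length = 140L, seed = 1L,
                           missing_rate = 0, id = "synthetic") {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  with_seed(seed, {
    seq_types <- sample(model$classes, length, replace = TRUE,
                        prob = model$freqs)
    m <- matrix(NA_real_, length, 7L,
                dimnames = list(NULL, canonical_shifts()))
    for (i in seq_len(length)) {
      k <- seq_types[i]
      mu <- model$means[k, ]; s <- model$sds[k, ]
      ok <- !is.na(mu)
      m[i, ok] <- stats::rnorm(sum(ok), mu[ok], s[ok])
    }
    if (missing_rate > 0) {
      present <- which(!is.na(m))
      drop <- present[stats::runif(length(present)) < missing_rate]
      m[drop] <- NA_real_
    }
  })
  df <- data.frame(id = sprintf("%s_%d", id, seq_len(length)),
                   residue_type = seq_types,
                   source = id,
                   sequence_position = seq_len(length),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(m))
  list(sequence = protein_seq(paste(seq_types, collapse = ""), id = id),
       spins = as_spin_table(df, warn = FALSE))
}

#' Sample spin-system chains from a simulated protein
#'
#' Draws contiguous runs of consecutive sequence positions.  In amide
#' (proton-detected) mode, chains never include a proline member —
#' sequential walks break at prolines — though the optional `pre`
#' residue may be one.
#'
#' @param sequence a [protein_seq()].
#' @param spins the protein's `spin_table` (with `sequence_position`).
#' @param n_chains how many chains.
#' @param length_range inclusive range of chain lengths.
#' @param seed RNG seed.
#' @param amide_mode forbid proline members.
#' @param include_pre attach the preceding residue as `pre` when one
#'   exists.
#' @return list of [ss_chain()]; each carries attributes `start`
#'   (1-based position of the first member) for test bookkeeping.
#' @export
sample_chains <- function(sequence, spins, n_chains = 10L,
                          length_range = c(3L, 7L), seed = 1L,
                          amide_mode = TRUE, include_pre = TRUE) {
  res <- residues(sequence)
  n <- length(res)
  ok_start <- function(s, len) {
    if (s < 1L || s + len - 1L > n) return(FALSE)
    !(amide_mode && any(res[s:(s + len - 1L)] == "P"))
  }
  chains <- vector("list", n_chains)
  with_seed(seed, {
    for (i in seq_len(n_chains)) {
      for (try in 1:1000) {
        len <- sample(length_range[1L]:length_range[2L], 1L)
        s <- sample.int(n - len + 1L, 1L)
        if (ok_start(s, len)) break
        if (try == 1000) stop("could not place a chain avoiding prolines")
      }
      members <- spins$id[match(s:(s + len - 1L), spins$sequence_position)]
      pre <- if (include_pre && s > 1L)
        spins$id[match(s - 1L, spins$sequence_position)]
      ch <- ss_chain(sprintf("chain%02d", i), members, pre = pre)
      attr(ch, "start") <- s
      chains[[i]] <- ch
    }
  })
  chains
}

#' Simulated HSQC-style peak list for a protein
#'
#' One (N, HN) peak per residue having both shifts; labels follow the
#' residue-pair convention `X##-Y##` (preceding residue first) used by
#' [transfer_assignments()].
#'
#' @param spins a `spin_table` with `sequence_position` and
#'   `residue_type`.
#' @param sequence the matching [protein_seq()].
#' @return A `peak_list` data.frame.
#' @export
peaks_from_spins <- function(spins, sequence) {
  res <- residues(sequence)
  keep <- which(!is.na(spins$N) & !is.na(spins$HN))
  pos <- spins$sequence_position[keep]
  lab <- ifelse(pos > 1L,
                sprintf("%s%d-%s%d", res[pmax(pos - 1L, 1L)], pos - 1L,
                        res[pos], pos),
                sprintf("%s%d", res[pos], pos))
  out <- data.frame(label = lab, n_ppm = spins$N[keep],
                    h_ppm = spins$HN[keep], stringsAsFactors = FALSE)
  class(out) <- c("peak_list", class(out))
  out
}

#' Jitter peak positions
#'
#' Adds independent Gaussian noise per axis, emulating the peak movement
#' between samples measured under slightly different conditions.  Labels
#' are preserved; zero standard deviations return the input unchanged.
#'
#' @param peaks a `peak_list`.
#' @param h_sd,n_sd noise standard deviations (ppm).
#' @param seed RNG seed.
#' @return The jittered `peak_list`.
#' @export
jitter_peaks <- function(peaks, h_sd = 0.02, n_sd = 0.1, seed = 1L) {
  with_seed(seed, {
    peaks$h_ppm <- peaks$h_ppm + stats::rnorm(nrow(peaks), 0, h_sd)
    peaks$n_ppm <- peaks$n_ppm + stats::rnorm(nrow(peaks), 0, n_sd)
  })
  peaks
}

#' Shrink class scatter to control separability
#'
#' Convenience for tests: returns a copy of the model with all standard
#' deviations multiplied by `factor`, so class means sit `1/factor`
#' times as many pooled standard deviations apart.
#'
#' @param model a `class_model`.
#' @param factor multiplicative factor on all sds.
#' @return A `class_model`.
#' @export
scale_model_sds <- function(model, factor) {
  model$sds <- model$sds * factor
  model
}
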