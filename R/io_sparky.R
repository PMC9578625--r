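# Sparky .list peak lists: "Assignment  w1  w2" with w1 = 15N and
# w2 = 1H (ppm) for an 15N-HSQC.

#' Read a Sparky 2D peak list
#'
#' Parses the Sparky `.list` dialect: an assignment column followed by
#' w1 (N, ppm) and w2 (H, ppm).  A header line starting with
#' "Assignment" is skipped; a label of `?` (or any all-`?` pattern like
#' `?-?`) means an unlabeled peak.
#'
#' @param path file path.
#' @return data.frame (class `peak_list`) with columns `label`
#'   (NA when unlabeled), `n_ppm`, `h_ppm`.
#' @export
parse_sparky_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*Assignment", lines))
  label <- character(0); n_ppm <- numeric(0); h_ppm <- numeric(0)
  for (i in keep) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 3L)
      stop("line ", i, " of ", path, ": expected `label w1 w2`")
    w1 <- suppressWarnings(as.numeric(tok[2L]))
    w2 <- suppressWarnings(as.numeric(tok[3L]))
    if (is.na(w1) || is.na(w2))
      stop("line ", i, " of ", path, ": non-numeric peak coordinate")
    lab <- tok[1L]
    if (grepl("^[?-]+$", lab)) lab <- NA_character_
    label <- c(label, lab); n_ppm <- c(n_ppm, w1); h_ppm <- c(h_ppm, w2)
  }
  out <- data.frame(label = label, n_ppm = n_ppm, h_ppm = h_ppm,
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_list", class(out))
  out
}

#' Write a Sparky 2D peak list
#' @param peaks data.frame with `label`, `n_ppm`, `h_ppm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sparky_list <- function(peaks, path) {
  lab <- ifelse(is.na(peaks$label), "?", peaks$label)
  lines <- c(sprintf("%17s %8s %8s", "Assignment", "w1", "w2"),
             sprintf("%17s %8.3f %8.3f", lab, peaks$n_ppm, peaks$h_ppm))
  writeLines(lines, path)
  invisible(path)
}
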