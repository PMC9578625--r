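# FASTA protein sequences (read via Biostrings).

#' Protein sequence object
#'
#' @param seq one-letter residue string (case-insensitive).
#' @param id identifier.
#' @return A `protein_seq`: list with `id` and uppercase `seq`.
#' @export
protein_seq <- function(seq, id = "seq") {
  seq <- toupper(gsub("[[:space:]]", "", seq))
  bad <- setdiff(strsplit(seq, "")[[1]], aa_alphabet())
  if (length(bad))
    stop("non-standard residue letter(s): ", paste(unique(bad), collapse = ", "))
  structure(list(id = as.character(id), seq = seq), class = "protein_seq")
}

#' @export
print.protein_seq <- function(x, ...) {
  cat("protein_seq ", x$id, " (", nchar(x$seq), " aa)\n", sep = "")
  invisible(x)
}

#' Residues of a protein sequence
#' @param x a `protein_seq`.
#' @return Character vector of one-letter codes.
#' @export
residues <- function(x) strsplit(x$seq, "")[[1]]

#' Read a protein sequence from FASTA
#'
#' Single- or multi-record FASTA; the first record is used unless `id`
#' names another one.  Lowercase letters are normalized to uppercase;
#' non-standard letters are rejected.
#'
#' @param path FASTA file.
#' @param id optional record identifier to select.
#' @return A [protein_seq()].
#' @export
parse_fasta <- function(path, id = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  if (!is.null(id)) {
    hit <- which(sub("\\s.*$", "", names(set)) == id)
    if (!length(hit)) stop("no FASTA record named ", id, " in ", path)
    rec <- set[hit[1L]]
  } else {
    rec <- set[1L]
  }
  protein_seq(as.character(rec[[1L]]), id = sub("\\s.*$", "", names(rec)))
}

#' Write a protein sequence as FASTA
#' @param x a `protein_seq`.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  lines <- c(paste0(">", x$id),
             substring(x$seq, seq(1L, nchar(x$seq), width),
                       pmin(seq(1L, nchar(x$seq), width) + width - 1L,
                            nchar(x$seq))))
  writeLines(lines, path)
  invisible(path)
}
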