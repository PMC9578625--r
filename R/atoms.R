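# Canonical shift names, residue alphabet, shift subsets and the
# atom-name normalization table.

#' Canonical chemical-shift names
#'
#' The seven chemical shifts a spin system may carry, in the fixed column
#' order used throughout the package: amide proton (HN), amide nitrogen
#' (N), carbonyl carbon (CO), alpha carbon (CA), beta carbon (CB), alpha
#' proton (HA) and beta proton (HB).
#'
#' @return Character vector of length 7.
#' @export
canonical_shifts <- function() {
  c("HN", "N", "CO", "CA", "CB", "HA", "HB")
}

#' One-letter amino-acid alphabet
#' @return The 20 standard one-letter codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Shifts that are structurally absent for a residue type: glycine has no
# beta carbon or beta proton, proline has no amide proton.
STRUCTURAL_ABSENT <- list(G = c("CB", "HB"), P = "HN")

#' Shifts structurally absent for a residue type
#'
#' @param residue_type one-letter code (vectorized).
#' @return For a single code, a character vector (possibly empty); for
#'   several codes, a named list.
#' @export
structural_absences <- function(residue_type) {
  out <- lapply(residue_type, function(r) {
    a <- STRUCTURAL_ABSENT[[r]]
    if (is.null(a)) character(0) else a
  })
  if (length(residue_type) == 1L) out[[1L]] else stats::setNames(out, residue_type)
}

#' Define a chemical-shift subset
#'
#' Three standard subsets map onto typical experimental setups:
#' subset `"i"` = (HN, N, CA, CO), obtainable from 4D HNCACO + 4D HNCOCA;
#' subset `"ii"` = (CA, CB, HA, HB), obtainable from a single
#' 4D HabCab(CO)NH; subset `"iii"` = all seven shifts.  A custom subset
#' may be given as any duplicate-free selection of canonical names.
#'
#' @param name `"i"`, `"ii"`, `"iii"`, or `"custom"`.
#' @param shift_names for `"custom"`, the ordered shift names.
#' @return A character vector of shift names with attribute `subset_name`,
#'   class `shift_subset`.
#' @export
shift_subset <- function(name = c("iii", "i", "ii", "custom"),
                         shift_names = NULL) {
  name <- match.arg(name)
  sets <- list(
    i   = c("HN", "N", "CA", "CO"),
    ii  = c("CA", "CB", "HA", "HB"),
    iii = canonical_shifts()
  )
  if (name == "custom") {
    if (is.null(shift_names))
      stop("custom subset requires `shift_names`")
    shift_names <- as.character(shift_names)
    bad <- setdiff(shift_names, canonical_shifts())
    if (length(bad))
      stop("unknown shift name(s): ", paste(bad, collapse = ", "),
           "; accepted: ", paste(canonical_shifts(), collapse = ", "))
    if (anyDuplicated(shift_names))
      stop("duplicate shift names in custom subset")
    out <- shift_names
  } else {
    out <- sets[[name]]
  }
  structure(out, subset_name = name, class = c("shift_subset", "character"))
}

as_shift_subset <- function(x) {
  if (inherits(x, "shift_subset")) return(x)
  if (is.character(x) && length(x) == 1L && x %in% c("i", "ii", "iii"))
    return(shift_subset(x))
  shift_subset("custom", shift_names = x)
}

#' @export
print.shift_subset <- function(x, ...) {
  cat("shift subset (", attr(x, "subset_name"), "): ",
      paste(unclass(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Atom-name normalization table
#'
#' Maps raw atom names found in NMR-STAR loops or table headers to the
#' seven canonical shift names.  Stereo pairs (HB2/HB3, and glycine
#' HA2/HA3) collapse to a single value by arithmetic mean; a lone member
#' of a pair is used as-is.  The table ships as versioned data in
#' `extdata/atom_name_map.tsv`.
#'
#' @return data.frame with columns `raw`, `canonical`, `combine`.
#' @export
atom_name_map <- function() {
  path <- system.file("extdata", "atom_name_map.tsv", package = "shiftlda",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Three-letter -> one-letter residue codes (parse-time convenience).
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

normalize_residue_code <- function(x) {
  x <- toupper(trimws(x))
  out <- ifelse(nchar(x) == 3L, unname(AA3TO1[x]), x)
  out[!(out %in% aa_alphabet())] <- NA_character_
  out
}
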