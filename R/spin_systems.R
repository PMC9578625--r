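# Spin-system tables: the package-wide container for (possibly
# incomplete) chemical-shift records.

#' Build a spin-system table
#'
#' A spin-system table is a data.frame with one row per spin system and
#' columns `id`, `residue_type` (one-letter code or NA), `source`
#' (protein or entry identifier, or NA), `sequence_position` (integer or
#' NA) and one numeric column per canonical shift (`HN`, `N`, `CO`, `CA`,
#' `CB`, `HA`, `HB`), where `NA` means the shift was not observed.
#' Missing values are always represented by `NA`, never by sentinel
#' numbers.  Extra columns (e.g. raw `HB2`/`HB3` before stereo collapse)
#' are preserved.
#'
#' @param id character identifiers (unique).
#' @param residue_type optional one- or three-letter codes.
#' @param source optional protein/entry identifier(s).
#' @param sequence_position optional integer positions.
#' @param ... named numeric vectors for canonical shifts, e.g. `CA = ...`.
#' @param warn warn when a glycine/proline structural invariant is
#'   violated (the offending shift is kept; callers decide).
#' @return A `spin_table` (data.frame subclass).
#' @export
spin_table <- function(id, residue_type = NA, source = NA,
                       sequence_position = NA, ..., warn = TRUE) {
  shifts <- list(...)
  n <- length(id)
  bad <- setdiff(names(shifts), canonical_shifts())
  if (length(bad))
    stop("unknown shift column(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(canonical_shifts(), collapse = ", "))
  df <- data.frame(
    id = as.character(id),
    residue_type = rep_len(normalize_residue_code(as.character(residue_type)), n),
    source = rep_len(as.character(source), n),
    sequence_position = rep_len(as.integer(sequence_position), n),
    stringsAsFactors = FALSE
  )
  for (s in canonical_shifts())
    df[[s]] <- if (s %in% names(shifts)) rep_len(as.numeric(shifts[[s]]), n) else NA_real_
  as_spin_table(df, warn = warn)
}

#' Coerce a data.frame to a spin-system table
#'
#' Validates shift values (finite or NA), fills absent metadata and shift
#' columns, and checks the glycine/proline structural invariants.
#'
#' @param df data.frame with at least an `id` column.
#' @param warn warn on structural-invariant violations.
#' @return A `spin_table`.
#' @export
as_spin_table <- function(df, warn = TRUE) {
  if (!"id" %in% names(df)) stop("spin table requires an `id` column")
  df$id <- as.character(df$id)
  if (!"residue_type" %in% names(df)) df$residue_type <- NA_character_
  df$residue_type <- normalize_residue_code(as.character(df$residue_type))
  if (!"source" %in% names(df)) df$source <- NA_character_
  if (!"sequence_position" %in% names(df)) df$sequence_position <- NA_integer_
  df$sequence_position <- as.integer(df$sequence_position)
  for (s in canonical_shifts()) {
    if (!s %in% names(df)) df[[s]] <- NA_real_
    df[[s]] <- as.numeric(df[[s]])
    if (any(!is.na(df[[s]]) & !is.finite(df[[s]])))
      stop("non-finite value in shift column ", s)
  }
  meta <- c("id", "residue_type", "source", "sequence_position")
  extra <- setdiff(names(df), c(meta, canonical_shifts()))
  df <- df[, c(meta, canonical_shifts(), extra), drop = FALSE]
  if (warn) check_structural_invariants(df)
  rownames(df) <- NULL
  class(df) <- unique(c("spin_table", class(df)))
  df
}

# Warn (once per rule) about typed spin systems carrying shifts their
# residue type cannot have.
check_structural_invariants <- function(df) {
  for (type in names(STRUCTURAL_ABSENT)) {
    rows <- which(!is.na(df$residue_type) & df$residue_type == type)
    if (!length(rows)) next
    for (s in STRUCTURAL_ABSENT[[type]]) {
      offenders <- rows[!is.na(df[[s]][rows])]
      if (length(offenders))
        warning(sprintf("%d %s spin system(s) carry a %s shift (%s lacks %s)",
                        length(offenders), type, s, type, s),
                call. = FALSE)
    }
  }
  invisible(df)
}

#' Shift matrix of a spin-system table
#'
#' @param spins a `spin_table`.
#' @param shift_names columns to extract (default all seven).
#' @return Numeric matrix (rows named by spin-system id) with NA for
#'   missing shifts.
#' @export
shift_matrix <- function(spins, shift_names = canonical_shifts()) {
  m <- as.matrix(as.data.frame(spins)[, shift_names, drop = FALSE])
  rownames(m) <- spins$id
  storage.mode(m) <- "double"
  m
}

#' Which spin systems are complete for a subset?
#'
#' A spin system is complete when every subset shift is present, except
#' that with `respect_structure = TRUE` shifts structurally absent for
#' the (known) residue type — CB/HB for glycine, HN for proline — are not
#' required.
#'
#' @param spins a `spin_table`.
#' @param subset a [shift_subset()] or its name.
#' @param respect_structure exempt Gly CB/HB and Pro HN.
#' @return Logical vector.
#' @export
is_complete <- function(spins, subset, respect_structure = FALSE) {
  subset <- as_shift_subset(subset)
  m <- shift_matrix(spins, subset)
  present <- !is.na(m)
  if (!respect_structure) return(rowSums(present) == length(subset))
  required <- matrix(TRUE, nrow(m), ncol(m), dimnames = dimnames(m))
  for (type in names(STRUCTURAL_ABSENT)) {
    rows <- which(!is.na(spins$residue_type) & spins$residue_type == type)
    cols <- intersect(STRUCTURAL_ABSENT[[type]], colnames(m))
    if (length(rows) && length(cols)) required[rows, cols] <- FALSE
  }
  rowSums(present | !required) == length(subset)
}

#' Present-shift pattern per spin system
#'
#' @param spins a `spin_table`.
#' @param subset restrict to these shifts.
#' @return Character vector: comma-joined present shift names (in subset
#'   order), "" when none.
#' @export
shift_pattern <- function(spins, subset = canonical_shifts()) {
  subset <- as_shift_subset(subset)
  m <- shift_matrix(spins, subset)
  apply(!is.na(m), 1L, function(p) paste(subset[p], collapse = ","))
}
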