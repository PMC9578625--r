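# Plain tabular spin-system I/O (CSV/TSV, delimiter chosen by extension).

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read spin systems from a delimited table
#'
#' Expects a header row naming `id`, optionally `residue_type` (or
#' `type`), `source`, `sequence_position` (or `position`), and any of the
#' seven shift columns.  Raw atom names from the normalization table are
#' also accepted (`H` for HN, `C` for CO, `HB2`/`HB3` which collapse to
#' `HB` by arithmetic mean with the raw columns preserved).  Empty cells
#' are missing shifts.  Comma or tab delimiter is chosen by extension
#' (`.csv` = comma, otherwise tab).
#'
#' @param path file path.
#' @return A [spin_table()].
#' @export
parse_tabular_spin_systems <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"), comment.char = "#")
  names(df)[names(df) == "type"] <- "residue_type"
  names(df)[names(df) == "position"] <- "sequence_position"
  map <- atom_name_map()
  meta <- c("id", "residue_type", "source", "sequence_position")
  accepted <- c(meta, map$raw)
  unknown <- setdiff(names(df), accepted)
  if (length(unknown))
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "),
         "; accepted names: ", paste(accepted, collapse = ", "))
  out <- df[, intersect(meta, names(df)), drop = FALSE]
  for (canon in canonical_shifts()) {
    raws <- intersect(map$raw[map$canonical == canon], names(df))
    if (!length(raws)) next
    vals <- as.matrix(df[, raws, drop = FALSE])
    storage.mode(vals) <- "double"
    out[[canon]] <- rowMeans(vals, na.rm = TRUE)
    out[[canon]][is.nan(out[[canon]])] <- NA_real_
  }
  # keep raw stereo columns so structural exclusions can see them
  for (raw in intersect(c("HB2", "HB3"), names(df)))
    out[[raw]] <- as.numeric(df[[raw]])
  as_spin_table(out)
}

#' Write a spin-system table
#'
#' Writes `id`, `residue_type`, `source`, `sequence_position` and the
#' seven shift columns; missing values become empty cells.  Reading the
#' file back with [parse_tabular_spin_systems()] round-trips.
#'
#' @param spins a `spin_table`.
#' @param path output path (`.csv` = comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_spin_table <- function(spins, path) {
  cols <- c("id", "residue_type", "source", "sequence_position",
            canonical_shifts())
  df <- as.data.frame(spins)[, cols, drop = FALSE]
  utils::write.table(df, path, sep = delim_for(path), na = "",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generic report table
#'
#' TSV/CSV writer used by the command-line subcommands; delimiter chosen
#' by extension, `NA` written as empty cells.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = delim_for(path), na = "",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
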