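# Minimal NMR-STAR (v2 / v3) reader for assigned chemical-shift loops.
# Only the star features these loops actually use are supported:
# loop_/stop_ blocks, quoted tokens, comments.  No mmCIF-style frames
# beyond save_ pass-through is needed to recover the shift table.

star_tokens <- function(line) {
  # split one data line into tokens, honoring '...' and "..." quoting
  tokens <- character(0)
  rest <- trimws(line)
  while (nzchar(rest)) {
    ch <- substr(rest, 1L, 1L)
    if (ch %in% c("'", '"')) {
      m <- regmatches(rest, regexpr(paste0("^", ch, "[^", ch, "]*", ch), rest))
      if (!length(m)) { tokens <- c(tokens, rest); break }
      tokens <- c(tokens, substr(m, 2L, nchar(m) - 1L))
      rest <- trimws(substr(rest, nchar(m) + 1L, nchar(rest)))
    } else {
      m <- regmatches(rest, regexpr("^\\S+", rest))
      if (m == "#") break  # trailing comment
      tokens <- c(tokens, m)
      rest <- trimws(substr(rest, nchar(m) + 1L, nchar(rest)))
    }
  }
  tokens
}

# Return all loops as list(tags = character, rows = character matrix).
star_loops <- function(lines) {
  loops <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && grepl("^\\s*_", lines[i])) {
        tags <- c(tags, sub("^\\s*(\\S+).*$", "\\1", lines[i]))
        i <- i + 1L
      }
      buf <- character(0)
      rows <- list()
      while (i <= n && !grepl("^\\s*(stop_|loop_)\\s*$", lines[i])) {
        ln <- lines[i]
        if (!grepl("^\\s*#", ln) && nzchar(trimws(ln))) {
          buf <- c(buf, star_tokens(ln))
          while (length(buf) >= length(tags)) {
            rows[[length(rows) + 1L]] <- buf[seq_len(length(tags))]
            buf <- buf[-seq_len(length(tags))]
          }
        }
        i <- i + 1L
      }
      if (length(tags) && length(rows))
        loops[[length(loops) + 1L]] <-
          list(tags = tags, rows = do.call(rbind, rows))
    }
    i <- i + 1L
  }
  loops
}

#' Read assigned chemical shifts from an NMR-STAR entry
#'
#' Supports both NMR-STAR 3 (`_Atom_chem_shift.*` loop) and NMR-STAR 2
#' (`_Chem_shift_value` loop).  Atom names are normalized to the seven
#' canonical shifts via [atom_name_map()]: H becomes HN, C becomes CO,
#' and stereo pairs HB2/HB3 (or glycine HA2/HA3) collapse to one value by
#' arithmetic mean (raw HB2/HB3 are preserved as extra columns).
#' Ambiguity codes are ignored.  Atoms outside the map are ignored;
#' residues with unknown residue codes are skipped with a warning.
#'
#' @param path NMR-STAR file.
#' @param entry_id identifier stored in the `source` column (default: the
#'   file's `data_` block name, or the file name).
#' @return A [spin_table()], one row per residue having at least one
#'   canonical shift.
#' @export
parse_nmrstar_shifts <- function(path, entry_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (is.null(entry_id)) {
    dl <- grep("^data_", lines, value = TRUE)
    entry_id <- if (length(dl)) sub("^data_", "", dl[1L]) else basename(path)
  }
  loops <- star_loops(lines)
  pick <- NULL
  for (lp in loops) {
    if (any(grepl("^_Atom_chem_shift\\.Val$", lp$tags)) ||
        any(lp$tags == "_Chem_shift_value")) { pick <- lp; break }
  }
  if (is.null(pick))
    stop("no assigned chemical-shift loop found in entry ", entry_id,
         " (", path, ")")
  tagcol <- function(...) {
    for (t in c(...)) { j <- which(pick$tags == t); if (length(j)) return(j[1L]) }
    NA_integer_
  }
  j_seq  <- tagcol("_Atom_chem_shift.Seq_ID", "_Atom_chem_shift.Comp_index_ID",
                   "_Residue_seq_code")
  j_res  <- tagcol("_Atom_chem_shift.Comp_ID", "_Residue_label")
  j_atom <- tagcol("_Atom_chem_shift.Atom_ID", "_Atom_name")
  j_val  <- tagcol("_Atom_chem_shift.Val", "_Chem_shift_value")
  j_ent  <- tagcol("_Atom_chem_shift.Entity_ID")
  if (anyNA(c(j_seq, j_res, j_atom, j_val)))
    stop("chemical-shift loop in entry ", entry_id,
         " lacks residue/atom/value tags")
  rows <- pick$rows
  seqpos <- suppressWarnings(as.integer(rows[, j_seq]))
  res3 <- toupper(rows[, j_res])
  atom <- toupper(rows[, j_atom])
  val <- suppressWarnings(as.numeric(rows[, j_val]))
  ent <- if (!is.na(j_ent)) rows[, j_ent] else rep("1", nrow(rows))
  keep <- !is.na(seqpos) & !is.na(val)
  res1 <- normalize_residue_code(res3)
  unk <- keep & is.na(res1)
  if (any(unk)) {
    warning("entry ", entry_id, ": skipping residue(s) with unknown code(s): ",
            paste(unique(res3[unk]), collapse = ", "), call. = FALSE)
    keep <- keep & !unk
  }
  map <- atom_name_map()
  canon <- map$canonical[match(atom, map$raw)]
  keep_atom <- keep & !is.na(canon)
  key <- paste(ent, seqpos, sep = ".")
  ids <- unique(key[keep])
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  out$residue_type <- res1[match(ids, key)]
  out$source <- entry_id
  out$sequence_position <- seqpos[match(ids, key)]
  for (cshift in canonical_shifts()) {
    sel <- keep_atom & canon == cshift
    out[[cshift]] <- vapply(ids, function(k) {
      v <- val[sel & key == k]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  for (raw in c("HB2", "HB3")) {
    sel <- keep & atom == raw
    if (!any(sel)) next
    out[[raw]] <- val[sel][match(ids, key[sel])]
  }
  has_shift <- rowSums(!is.na(out[, canonical_shifts(), drop = FALSE])) > 0
  out <- out[has_shift, , drop = FALSE]
  out <- out[order(out$sequence_position), , drop = FALSE]
  as_spin_table(out)
}
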