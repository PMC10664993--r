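# Chemical-shift table I/O: five-column prot-style text and a minimal
# NMR-STAR v3 _Atom_chem_shift loop.

#' Read a prot-style chemical shift table
#'
#' Five whitespace-separated columns: index, shift (ppm), sd (ppm),
#' atom name, residue number. `#` comments and blank lines are skipped;
#' a shift of 999.000 denotes an unassigned atom and is dropped.
#'
#' @param path Input path.
#' @return Tibble `residue_number`, `atom_name`, `shift`, `sd`.
#' @export
read_shifts_prot <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  ok <- vapply(parts, length, 0L) >= 5
  parts <- parts[ok]
  out <- tibble::tibble(
    residue_number = as.integer(vapply(parts, `[`, "", 5)),
    atom_name = normalize_atom_name(vapply(parts, `[`, "", 4)),
    shift = as.numeric(vapply(parts, `[`, "", 2)),
    sd = as.numeric(vapply(parts, `[`, "", 3))
  )
  dplyr::filter(out, .data$shift < 999)
}

#' Write a prot-style chemical shift table
#'
#' @param shifts Tibble with `residue_number`, `atom_name`, `shift` and
#'   optionally `sd` (0 if absent) and `class` (appended as a trailing
#'   comment column when present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shifts_prot <- function(shifts, path) {
  sd <- if ("sd" %in% names(shifts)) shifts$sd else rep(0, nrow(shifts))
  sd[is.na(sd)] <- 0
  cls <- if ("class" %in% names(shifts)) paste0("  # ", shifts$class) else ""
  lines <- sprintf("%4d %8.3f %6.3f %-6s %4d%s",
                   seq_len(nrow(shifts)), shifts$shift, sd,
                   shifts$atom_name, shifts$residue_number, cls)
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal NMR-STAR v3 chemical shift loop
#'
#' Parses the `_Atom_chem_shift` loop of an NMR-STAR v3 file, using the
#' `Seq_ID`, `Atom_ID`, `Val` and (if present) `Val_err` tags. Only the
#' first such loop is read.
#'
#' @param path Input path.
#' @return Tibble `residue_number`, `atom_name`, `shift`, `sd`.
#' @export
read_shifts_star <- function(path) {
  lines <- readLines(path)
  li <- which(trimws(lines) == "loop_")
  for (start in li) {
    i <- start + 1
    tags <- character(0)
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    field <- sub("^_Atom_chem_shift\\.", "", tags)
    rows <- list()
    while (i <= length(lines)) {
      l <- trimws(lines[i])
      if (l == "stop_") break
      if (nzchar(l) && !startsWith(l, "#")) rows[[length(rows) + 1]] <-
          strsplit(l, "[[:space:]]+")[[1]]
      i <- i + 1
    }
    rows <- rows[vapply(rows, length, 0L) == length(field)]
    get <- function(tag) vapply(rows, `[`, "", match(tag, field))
    err <- if ("Val_err" %in% field) {
      suppressWarnings(as.numeric(get("Val_err")))
    } else rep(NA_real_, length(rows))
    return(tibble::tibble(
      residue_number = as.integer(get("Seq_ID")),
      atom_name = normalize_atom_name(get("Atom_ID")),
      shift = as.numeric(get("Val")),
      sd = err
    ))
  }
  stop("no _Atom_chem_shift loop found in ", path, call. = FALSE)
}

#' Write a minimal NMR-STAR v3 chemical shift loop
#'
#' @param shifts Tibble with `residue_number`, `residue_type` (optional),
#'   `atom_name`, `shift`, optional `sd`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shifts_star <- function(shifts, path) {
  rt <- if ("residue_type" %in% names(shifts)) shifts$residue_type else "."
  sd <- if ("sd" %in% names(shifts)) shifts$sd else NA_real_
  sd <- ifelse(is.na(sd), ".", sprintf("%.3f", sd))
  nuc <- nucleus_of(shifts$atom_name)
  lines <- c(
    "data_shiftassign", "", "save_assigned_chemical_shifts", "loop_",
    "   _Atom_chem_shift.ID", "   _Atom_chem_shift.Seq_ID",
    "   _Atom_chem_shift.Comp_ID", "   _Atom_chem_shift.Atom_ID",
    "   _Atom_chem_shift.Atom_type", "   _Atom_chem_shift.Val",
    "   _Atom_chem_shift.Val_err",
    sprintf("   %4d %4d %-4s %-6s %-2s %9.3f %s",
            seq_len(nrow(shifts)), shifts$residue_number, rt,
            shifts$atom_name, sub("^[0-9]+", "", nuc), shifts$shift, sd),
    "stop_", "save_"
  )
  writeLines(lines, path)
  invisible(path)
}
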