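#' Build a protein sequence table
#'
#' The sequence is represented as a tibble with one row per residue,
#' numbered consecutively. Input may be a single string of one-letter
#' codes or a character vector of three-letter codes.
#'
#' @param x One-letter string (e.g. `"MKVL"`) or character vector of
#'   three-letter codes (e.g. `c("MET","LYS")`).
#' @param first_residue_number Number of the first residue (default 1).
#' @return Tibble with columns `residue_number`, `residue_type`.
#' @export
#' @examples
#' protein_sequence("AGFV")
protein_sequence <- function(x, first_residue_number = 1L) {
  if (length(x) == 0L || (length(x) == 1L && !nzchar(x))) {
    stop("empty sequence", call. = FALSE)
  }
  if (length(x) == 1L && !x %in% AA3) {
    letters1 <- strsplit(toupper(x), "")[[1]]
    idx <- match(letters1, AA1)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      stop(sprintf("unknown residue code '%s' at position %d",
                   letters1[bad], bad), call. = FALSE)
    }
    res <- AA3[idx]
  } else {
    res <- toupper(x)
    bad <- which(!res %in% AA3)
    if (length(bad) > 0) {
      stop(sprintf("unknown residue code '%s' at position %d",
                   res[bad[1]], bad[1]), call. = FALSE)
    }
  }
  tibble::tibble(
    residue_number = seq.int(first_residue_number, length.out = length(res)),
    residue_type = res
  )
}

#' Read a single-record FASTA sequence file
#'
#' @param path Path to a FASTA file containing exactly one amino acid record.
#' @param first_residue_number Number assigned to the first residue.
#' @return Sequence tibble as from [protein_sequence()].
#' @export
read_sequence_fasta <- function(path, first_residue_number = 1L) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    if (length(ss) != 1L) {
      stop("expected exactly one FASTA record, found ", length(ss), call. = FALSE)
    }
    return(protein_sequence(as.character(ss[[1]]), first_residue_number))
  }
  lines <- readLines(path)
  heads <- grepl("^>", lines)
  if (sum(heads) != 1L) stop("expected exactly one FASTA record", call. = FALSE)
  protein_sequence(paste(gsub("\\s", "", lines[!heads]), collapse = ""),
                   first_residue_number)
}

#' Read a three-letter numbered sequence file
#'
#' One residue per line: `RES  number` (CYANA .seq convention). Lines
#' starting with `#` are ignored. Numbering must be strictly consecutive.
#'
#' @param path Path to the sequence file.
#' @return Sequence tibble as from [protein_sequence()].
#' @export
read_sequence_numbered <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty sequence file", call. = FALSE)
  parts <- strsplit(lines, "[[:space:]]+")
  res <- toupper(vapply(parts, `[`, "", 1))
  num <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
  if (anyNA(num)) num <- seq_along(res)
  if (!all(diff(num) == 1L)) {
    stop("residue numbering must be strictly consecutive", call. = FALSE)
  }
  protein_sequence(res, first_residue_number = num[1])
}

#' Write a three-letter numbered sequence file
#'
#' @param sequence Sequence tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequence_numbered <- function(sequence, path) {
  writeLines(sprintf("%-5s %d", sequence$residue_type,
                     sequence$residue_number), path)
  invisible(path)
}

check_sequence <- function(sequence) {
  stopifnot(is.data.frame(sequence),
            all(c("residue_number", "residue_type") %in% names(sequence)))
  if (nrow(sequence) == 0) stop("empty sequence", call. = FALSE)
  bad <- which(!sequence$residue_type %in% AA3)
  if (length(bad) > 0) {
    stop(sprintf("unknown residue code '%s' at position %d",
                 sequence$residue_type[bad[1]], bad[1]), call. = FALSE)
  }
  if (nrow(sequence) > 1 && !all(diff(sequence$residue_number) == 1L)) {
    stop("residue numbering must be strictly consecutive", call. = FALSE)
  }
  invisible(sequence)
}
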