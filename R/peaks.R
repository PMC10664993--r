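# Observed peak lists: XEASY / Sparky I/O and confidence-based selection.

#' Read an XEASY-style peak list
#'
#' Header line `# Number of dimensions N`; data rows contain the peak id,
#' N chemical shift positions (ppm), a color code (ignored), an intensity,
#' and the picker confidence score appended as the final column (assumed
#' 1.0 when absent).
#'
#' @param path Input path.
#' @param spectrum Spectrum name to attach to the list (default from a
#'   `# Spectrum` header comment, else the file name).
#' @return Peak tibble: `spectrum`, `id`, `w1`..`wN`, `intensity`,
#'   `confidence`.
#' @export
read_peaks_xeasy <- function(path, spectrum = NULL) {
  lines <- readLines(path)
  ndim_line <- grep("Number of dimensions", lines, value = TRUE)
  if (length(ndim_line) == 0) stop("not an XEASY peak list: ", path, call. = FALSE)
  ndim <- as.integer(sub(".*Number of dimensions[[:space:]]*", "", ndim_line[1]))
  if (is.null(spectrum)) {
    sp <- grep("^#\\s*Spectrum", lines, value = TRUE)
    spectrum <- if (length(sp) > 0) trimws(sub("^#\\s*Spectrum[: ]*", "", sp[1]))
                else sub("\\.[^.]*$", "", basename(path))
  }
  dat <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  parts <- strsplit(trimws(dat), "[[:space:]]+")
  parts <- parts[vapply(parts, length, 0L) >= ndim + 1]
  num <- function(k) as.numeric(vapply(parts, function(p)
    if (length(p) >= k) p[k] else NA_character_, ""))
  out <- tibble::tibble(spectrum = spectrum, id = as.integer(num(1)))
  for (d in seq_len(ndim)) out[[paste0("w", d)]] <- num(1 + d)
  nc <- vapply(parts, length, 0L)
  out$intensity <- ifelse(nc >= ndim + 3, num(ndim + 3), NA_real_)
  out$confidence <- ifelse(nc >= ndim + 4, num(ndim + 4), 1.0)
  out$confidence[is.na(out$confidence)] <- 1.0
  if (anyDuplicated(out$id)) stop("duplicate peak ids in ", path, call. = FALSE)
  out
}

#' Write an XEASY-style peak list
#'
#' @param peaks Peak tibble as from [read_peaks_xeasy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_xeasy <- function(peaks, path) {
  wc <- grep("^w[0-9]+$", names(peaks), value = TRUE)
  wc <- wc[vapply(wc, function(w) !all(is.na(peaks[[w]])), TRUE)]
  ndim <- length(wc)
  pos <- do.call(cbind, lapply(wc, function(w) sprintf("%8.3f", peaks[[w]])))
  inten <- ifelse(is.na(peaks$intensity), 0, peaks$intensity)
  lines <- c(sprintf("# Number of dimensions %d", ndim),
             sprintf("# Spectrum %s", peaks$spectrum[1] %||% "unknown"),
             sprintf("%5d %s  1 %12.4e %6.3f", peaks$id,
                     apply(pos, 1, paste, collapse = " "),
                     inten, peaks$confidence))
  if (nrow(peaks) == 0) lines <- lines[1:2]
  writeLines(lines, path)
  invisible(path)
}

#' Read a Sparky-style peak list
#'
#' Columns: assignment label, one position per dimension (ppm), and
#' optionally a height. Dimensionality is inferred from the header or the
#' first data row.
#'
#' @param path Input path.
#' @param spectrum Spectrum name to attach (default: file name).
#' @return Peak tibble as from [read_peaks_xeasy()] (confidence 1.0).
#' @export
read_peaks_sparky <- function(path, spectrum = NULL) {
  if (is.null(spectrum)) spectrum <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && grepl("^Assignment", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  parts <- strsplit(lines, "[[:space:]]+")
  nums <- lapply(parts, function(p) suppressWarnings(as.numeric(p[-1])))
  ncol <- min(vapply(nums, function(x) sum(!is.na(x)), 0L))
  ndim <- if (ncol >= 4) 3L else min(ncol, 3L)
  has_height <- ncol > ndim
  out <- tibble::tibble(spectrum = spectrum, id = seq_along(parts))
  for (d in seq_len(ndim)) out[[paste0("w", d)]] <-
    vapply(nums, function(x) x[d], 0)
  out$intensity <- if (has_height) vapply(nums, function(x) x[ndim + 1], 0) else NA_real_
  out$confidence <- 1.0
  out
}

#' Write a Sparky-style peak list
#'
#' @param peaks Peak tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_sparky <- function(peaks, path) {
  wc <- grep("^w[0-9]+$", names(peaks), value = TRUE)
  wc <- wc[vapply(wc, function(w) !all(is.na(peaks[[w]])), TRUE)]
  pos <- do.call(cbind, lapply(wc, function(w) sprintf("%9.3f", peaks[[w]])))
  inten <- ifelse(is.na(peaks$intensity), 0, peaks$intensity)
  hdr <- paste0("Assignment ", paste(sprintf("      w%d", seq_along(wc)),
                                     collapse = ""), "    Height")
  lines <- c(hdr, sprintf("%10s %s %12.4e", strrep("?-", length(wc) - 1) |>
                            paste0("?"), apply(pos, 1, paste, collapse = " "),
                          inten))
  if (nrow(peaks) == 0) lines <- lines[1]
  writeLines(lines, path)
  invisible(path)
}

#' Select observed peaks by picker confidence
#'
#' For through-bond spectra, keeps the `expected_count` highest-confidence
#' peaks (ties broken by larger intensity, then smaller id); for NOESY
#' spectra, keeps every peak with confidence at or above the fixed 0.1
#' threshold. The original ordering of retained peaks is preserved.
#'
#' @param peaks Peak tibble.
#' @param expected_count Number of expected peaks (required for
#'   through-bond spectra).
#' @param kind `"through-bond"` or `"NOESY"`; default looked up from the
#'   spectrum library by the list's spectrum name.
#' @param noesy_threshold Confidence threshold for NOESY peaks (0.1).
#' @return Filtered peak tibble.
#' @export
select_observed_peaks <- function(peaks, expected_count = NULL, kind = NULL,
                                  noesy_threshold = 0.1) {
  if (nrow(peaks) == 0) return(peaks)
  if (is.null(kind)) kind <- spectrum_definition(peaks$spectrum[1])$kind
  if (kind == "NOESY") {
    return(peaks[peaks$confidence >= noesy_threshold, ])
  }
  if (is.null(expected_count)) {
    stop("expected_count is required for through-bond spectra", call. = FALSE)
  }
  if (expected_count < 0) stop("expected_count must be >= 0", call. = FALSE)
  if (expected_count >= nrow(peaks)) return(peaks)
  inten <- ifelse(is.na(peaks$intensity), -Inf, peaks$intensity)
  ord <- order(-peaks$confidence, -inten, peaks$id)
  keep <- sort(ord[seq_len(expected_count)])
  peaks[keep, ]
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
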