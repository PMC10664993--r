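# Spectrum definitions: names, dimensions (nucleus + magnetization role),
# per-dimension tolerances and through-bond pathway probabilities.

.default_tol <- c("1H" = 0.03, "13C" = 0.4, "15N" = 0.4)

.spectrum_aliases <- c(
  "[1H,15N]-HSQC" = "N15HSQC", "15N-HSQC" = "N15HSQC", "HSQC15N" = "N15HSQC",
  "[1H,13C]-HSQC" = "C13HSQC", "13C-HSQC" = "C13HSQC", "HSQC13C" = "C13HSQC",
  "HN(CO)CA" = "HNcoCA", "HN(CA)CO" = "HNcaCO", "CBCA(CO)NH" = "CBCAcoNH",
  "HBHA(CO)NH" = "HBHAcoNH", "H(C)(CO)NH" = "hCcoNH", "(H)C(CO)NH" = "hCcoNH",
  "HCCH-TOCSY" = "HCCHTOCSY", "CCH-TOCSY" = "CCHTOCSY", "(H)CCH-TOCSY" = "CCHTOCSY",
  "15N-NOESY" = "N15NOESY", "N15-NOESY" = "N15NOESY",
  "13C-NOESY" = "C13NOESY", "C13-NOESY" = "C13NOESY"
)

#' Load the spectrum library
#'
#' Parses the bundled (or a user-supplied) spectrum library file defining
#' each supported experiment: its dimensions (nucleus and magnetization
#' role, with per-dimension tolerance), its kind (through-bond or NOESY),
#' the pathway template used to generate expected peaks, and the default
#' observation probabilities for strong and weak through-bond pathways.
#'
#' @param path Library file; defaults to the file shipped with the package.
#' @return Tibble with one row per experiment: `name`, `kind`, `template`,
#'   `n_dim`, `p_strong`, `p_weak`, and a list-column `dims` of per-dimension
#'   tibbles (`nucleus`, `role`, `tolerance`).
#' @export
spectrum_library <- function(path = system.file("extdata", "spectra.lib",
                                                package = "shiftassign")) {
  key <- paste0("speclib:", path)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- strsplit(lines, "[[:space:]]+")
  parse_dims <- function(s) {
    d <- strsplit(strsplit(s, ",")[[1]], ":")
    tibble::tibble(
      nucleus = vapply(d, `[`, "", 1),
      role = vapply(d, `[`, "", 2),
      tolerance = vapply(d, function(x) {
        if (length(x) >= 3) as.numeric(x[3]) else .default_tol[[x[1]]]
      }, 0)
    )
  }
  out <- tibble::tibble(
    name = vapply(rows, `[`, "", 1),
    kind = ifelse(vapply(rows, `[`, "", 2) == "noesy", "NOESY", "through-bond"),
    template = vapply(rows, `[`, "", 3),
    dims = lapply(rows, function(r) parse_dims(r[4])),
    p_strong = suppressWarnings(as.numeric(vapply(rows, `[`, "", 5))),
    p_weak = suppressWarnings(as.numeric(vapply(rows, `[`, "", 6)))
  )
  out$n_dim <- vapply(out$dims, nrow, 0L)
  .pkg_cache[[key]] <- out
  out
}

#' Look up one spectrum definition by name
#'
#' Common alternate spellings (`[1H,15N]-HSQC`, `CBCA(CO)NH`, `15N-NOESY`,
#' ...) are accepted.
#'
#' @param name Experiment name.
#' @param library Spectrum library tibble (default [spectrum_library()]).
#' @return One-row tibble from the library.
#' @export
spectrum_definition <- function(name, library = spectrum_library()) {
  canon <- if (name %in% names(.spectrum_aliases)) .spectrum_aliases[[name]] else name
  hit <- library[library$name == canon, ]
  if (nrow(hit) != 1) {
    stop(sprintf("unknown spectrum '%s'; supported types: %s", name,
                 paste(library$name, collapse = ", ")), call. = FALSE)
  }
  hit
}

#' Named dataset presets (spectrum combinations)
#'
#' Predefined experiment combinations used in the examples and benchmarks:
#' `triple` (classical triple-resonance backbone set), `optimal` (two HSQCs
#' plus CBCAcoNH, HCCH-TOCSY, CCH-TOCSY and both edited NOESYs), `noesy_only`
#' (HSQCs plus the two edited NOESYs) and `n15_only` (15N-HSQC plus
#' 15N-edited NOESY, for unlabeled-carbon samples).
#'
#' @param name Preset name.
#' @return Character vector of spectrum names.
#' @export
dataset_preset <- function(name = c("triple", "optimal", "noesy_only",
                                    "n15_only", "backbone_min")) {
  name <- match.arg(name)
  switch(name,
    triple = c("N15HSQC", "HNCA", "HNCO", "CBCANH", "CBCAcoNH"),
    optimal = c("N15HSQC", "C13HSQC", "CBCAcoNH", "HCCHTOCSY", "CCHTOCSY",
                "N15NOESY", "C13NOESY"),
    noesy_only = c("N15HSQC", "C13HSQC", "N15NOESY", "C13NOESY"),
    n15_only = c("N15HSQC", "N15NOESY"),
    backbone_min = c("N15HSQC", "HNCA")
  )
}
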