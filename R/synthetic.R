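# Convenience constructor of complete ground-truthed synthetic problems.

#' Random protein sequence
#'
#' Residue types drawn uniformly from a composition set (proline excluded
#' by default to keep every amide observable).
#'
#' @param n Number of residues.
#' @param seed Integer seed.
#' @param alphabet Residue pool (one-letter codes).
#' @return Sequence tibble.
#' @export
random_sequence <- function(n, seed = 1,
                            alphabet = c("A", "D", "E", "F", "G", "I", "K",
                                         "L", "N", "Q", "R", "S", "T", "V",
                                         "W", "Y")) {
  withr::with_seed(seed,
    protein_sequence(paste(sample(alphabet, n, replace = TRUE), collapse = "")))
}

#' Generate a complete synthetic assignment problem
#'
#' Builds a structure bundle, samples ground-truth shifts from the
#' statistical priors, back-calculates expected peaks for the requested
#' spectra (NOESY from the bundle) and simulates observed peak lists
#' under the noise model. Everything is seeded and reproducible.
#'
#' @param sequence Sequence tibble (or an integer: a [random_sequence()]
#'   of that length).
#' @param spectra Character vector of spectrum names (default the
#'   `triple` preset).
#' @param noise Noise model from [noise_model()].
#' @param structure_mode Conformation mode for [build_structure()].
#' @param n_conformers Conformers in the bundle.
#' @param seed Integer seed driving sequence, structure and truth.
#' @return List with `sequence`, `atom_set`, `priors`, `truth`, `bundle`,
#'   `expected`, `peaks` (observed tibble), and `reference` (the truth
#'   restricted to atoms, as an evaluation reference).
#' @export
synthetic_problem <- function(sequence, spectra = dataset_preset("triple"),
                              noise = noise_model(), structure_mode = "helix",
                              n_conformers = 3, seed = 1) {
  if (is.numeric(sequence) && length(sequence) == 1) {
    sequence <- random_sequence(sequence, seed = seed)
  }
  atom_set <- enumerate_atoms(sequence)
  priors <- statistical_priors(atom_set)
  truth <- sample_true_shifts(priors, seed = seed + 1)
  bundle <- build_structure(sequence, structure_mode,
                            n_conformers = n_conformers, seed = seed + 2)
  expected <- dplyr::bind_rows(lapply(spectra, function(sp) {
    sdef <- spectrum_definition(sp)
    if (sdef$kind == "NOESY") expected_noesy(bundle, atom_set, sdef)
    else expected_peaks_throughbond(sdef, atom_set)
  }))
  noise$seed <- seed + 3
  peaks <- simulate_peak_lists(expected, truth, noise)
  list(sequence = sequence, atom_set = atom_set, priors = priors,
       truth = truth, bundle = bundle, expected = expected, peaks = peaks,
       reference = truth)
}
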