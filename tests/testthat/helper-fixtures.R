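# Shared fixture builders: all synthetic, generated in code.

# A two-conformer bundle holding one HA(res i)-HN(res j) proton pair at
# prescribed distances (plus the amide N), far from everything else.
make_pair_bundle <- function(d1, d2, res_h = 2L, res_hn = 3L) {
  one <- function(cf, d) {
    tibble::tibble(
      conformer = cf,
      residue_number = c(res_h, res_hn, res_hn),
      residue_type = c("ALA", "ALA", "ALA"),
      atom_name = c("HA", "HN", "N"),
      element = c("H", "H", "N"),
      x = c(0, d, d + 0.8), y = 0, z = 0
    )
  }
  structure_bundle(dplyr::bind_rows(one(1, d1), one(2, d2)), label = "experimental")
}

# Atom subset matching make_pair_bundle.
pair_atom_set <- function() {
  atoms <- enumerate_atoms(protein_sequence("AAA"))
  atoms[(atoms$residue_number == 2 & atoms$atom_name == "HA") |
          (atoms$residue_number == 3 & atoms$atom_name %in% c("HN", "N")), ]
}

# A tiny observed peak list for a given spectrum.
make_peaks <- function(spectrum, pos, confidence = NULL, intensity = NULL,
                       ids = seq_len(nrow(pos))) {
  pos <- as.matrix(pos)
  out <- tibble::tibble(spectrum = spectrum, id = as.integer(ids))
  for (d in seq_len(ncol(pos))) out[[paste0("w", d)]] <- pos[, d]
  out$intensity <- intensity %||% rep(1, nrow(pos))
  out$confidence <- confidence %||% rep(1, nrow(pos))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small noiseless assignment instance built from known truth.
noiseless_instance <- function(n = 8, spectra = c("N15HSQC", "HNCA"),
                               seed = 1) {
  sq <- random_sequence(n, seed = seed)
  atoms <- enumerate_atoms(sq)
  pri <- statistical_priors(atoms)
  ex <- dplyr::bind_rows(lapply(spectra, function(sp)
    expected_peaks_throughbond(sp, atoms)))
  truth <- sample_true_shifts(pri, seed = seed + 1)
  obs <- simulate_peak_lists(ex, truth, noise_model(position_jitter = 0,
                                                    detection = FALSE,
                                                    artifact_rate = 0,
                                                    seed = seed + 2))
  list(sequence = sq, atoms = atoms, priors = pri, expected = ex,
       truth = truth, observed = obs)
}

# Consensus input: fake per-run shift tables for a single 1H atom.
fake_runs <- function(values) {
  lapply(values, function(v) {
    tibble::tibble(residue_number = 1L, atom_name = "HA", nucleus = "1H",
                   shift = v)
  })
}

expect_shift_equal <- function(solution, truth, tol = 1e-6) {
  tk <- atom_key(truth$residue_number, truth$atom_name)
  sk <- atom_key(solution$shifts$residue_number, solution$shifts$atom_name)
  err <- abs(solution$shifts$shift - truth$shift[match(sk, tk)])
  expect_true(all(err < tol))
}
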