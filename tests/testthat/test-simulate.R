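test_that("true shifts are seeded draws truncated at 3 sd", {
  atoms <- enumerate_atoms(random_sequence(10, seed = 2))
  pri <- statistical_priors(atoms)
  t1 <- sample_true_shifts(pri, seed = 5)
  t2 <- sample_true_shifts(pri, seed = 5)
  t3 <- sample_true_shifts(pri, seed = 6)
  expect_identical(t1, t2)
  expect_false(identical(t1$shift, t3$shift))
  expect_true(all(abs(t1$shift - pri$mean) <= 3 * pri$sd))
})

test_that("the sample mean of many draws approaches the prior mean", {
  pri <- tibble::tibble(residue_number = seq_len(4000), residue_type = "ALA",
                        atom_name = "CA", nucleus = "13C",
                        mean = 53.1, sd = 2.0)
  draws <- sample_true_shifts(pri, seed = 8)$shift
  se <- 2.0 / sqrt(4000)
  expect_lt(abs(mean(draws) - 53.1), 4 * se)
})

test_that("zero noise and full detection reproduce the truth exactly", {
  inst <- noiseless_instance(6, seed = 4)
  pk <- inst$observed
  expect_equal(nrow(pk), nrow(inst$expected))
  tm <- attr(pk, "truth_mapping")
  expect_equal(nrow(tm), nrow(inst$expected))
  tk <- atom_key(inst$truth$residue_number, inst$truth$atom_name)
  w1_true <- inst$truth$shift[match(atom_key(inst$expected$res1,
                                             inst$expected$atom1), tk)]
  expect_equal(pk$w1[order(pk$spectrum, pk$id)],
               w1_true[order(inst$expected$spectrum,
                             seq_len(nrow(inst$expected)))][order(sort(tm$obs_id))],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("artifact counts follow the binomial expectation", {
  inst <- noiseless_instance(10, spectra = "N15HSQC", seed = 3)
  n_expected <- nrow(inst$expected)
  counts <- vapply(1:40, function(s) {
    pk <- simulate_peak_lists(inst$expected, inst$truth,
                              noise_model(position_jitter = 0,
                                          detection = FALSE,
                                          artifact_rate = 0.5, seed = s))
    nrow(pk) - n_expected
  }, 0)
  m <- mean(counts)
  se <- sqrt(n_expected * 0.5 * 0.5 / 40)
  expect_lt(abs(m - 0.5 * n_expected), 5 * se)
})

test_that("detection thins peaks at the stated Bernoulli rate", {
  inst <- noiseless_instance(10, spectra = c("N15HSQC", "HNCA"), seed = 6)
  ex <- inst$expected
  ex$probability <- 0.9
  fr <- vapply(1:40, function(s) {
    pk <- simulate_peak_lists(ex, inst$truth,
                              noise_model(position_jitter = 0,
                                          detection = TRUE,
                                          artifact_rate = 0, seed = s))
    nrow(pk) / nrow(ex)
  }, 0)
  expect_lt(abs(mean(fr) - 0.9), 0.05)
})

test_that("positional jitter scales with the dimension tolerance", {
  inst <- noiseless_instance(10, spectra = "N15HSQC", seed = 9)
  pk <- simulate_peak_lists(inst$expected, inst$truth,
                            noise_model(position_jitter = 1 / 3,
                                        detection = FALSE,
                                        artifact_rate = 0, seed = 2))
  tm <- attr(pk, "truth_mapping")
  tk <- atom_key(inst$truth$residue_number, inst$truth$atom_name)
  h_true <- inst$truth$shift[match(atom_key(inst$expected$res1[tm$expected_row],
                                            inst$expected$atom1[tm$expected_row]),
                                   tk)]
  dev_h <- pk$w1[match(tm$obs_id, pk$id)] - h_true
  expect_lt(sd(dev_h), 3 * 0.01)
  expect_gt(sd(dev_h), 0.001)
})

test_that("decoys reach the target RMSD band in sub-Angstrom triplets", {
  sq <- random_sequence(12, seed = 13)
  b <- build_structure(sq, "helix", n_conformers = 1, seed = 13)
  d0 <- perturb_to_rmsd(b, 0, seed = 1)
  expect_equal(backbone_rmsd(b, d0), 0, tolerance = 1e-9)
  expect_equal(attr(d0, "label"), "decoy")

  d2 <- perturb_to_rmsd(b, 2.0, seed = 1)
  r <- backbone_rmsd(b, d2)
  expect_gte(r, 1.8)
  expect_lte(r, 2.2)
  confs <- lapply(sort(unique(d2$conformer)), function(cf)
    d2[d2$conformer == cf, ])
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(backbone_rmsd(confs[[i]], confs[[j]]), 1)
  }
})

test_that("domain concatenation joins with 10-glycine linkers", {
  d1 <- list(sequence = random_sequence(50, seed = 1))
  d2 <- list(sequence = random_sequence(60, seed = 2))
  comb <- concatenate_domains(list(d1, d2))
  expect_equal(nrow(comb$sequence), 120L)
  expect_equal(comb$sequence$residue_number, 1:120)
  expect_equal(comb$sequence$residue_type[51:60], rep("GLY", 10))

  d3 <- list(sequence = random_sequence(40, seed = 3))
  comb3 <- concatenate_domains(list(d1, d2, d3))
  expect_equal(nrow(comb3$sequence), 50 + 60 + 40 + 20)
  expect_error(concatenate_domains(list(d1)), "two domains")
})

test_that("concatenation merges peaks and truths without linker peaks", {
  p1 <- synthetic_problem(8, spectra = "N15HSQC", seed = 4)
  p2 <- synthetic_problem(9, spectra = "N15HSQC", seed = 5)
  comb <- concatenate_domains(list(
    list(sequence = p1$sequence, bundle = p1$bundle, truth = p1$truth,
         peaks = p1$peaks),
    list(sequence = p2$sequence, bundle = p2$bundle, truth = p2$truth,
         peaks = p2$peaks)))
  expect_equal(nrow(comb$peaks), nrow(p1$peaks) + nrow(p2$peaks))
  expect_false(anyDuplicated(comb$peaks$id) > 0)
  expect_equal(nrow(comb$truth), nrow(p1$truth) + nrow(p2$truth))
  # second domain truths renumbered beyond the linker
  expect_true(all(comb$truth$residue_number[seq_len(nrow(p1$truth))] <= 8))
  expect_true(all(comb$truth$residue_number[-seq_len(nrow(p1$truth))] >= 19))
  # bundle covers both domains and the linker
  expect_equal(sort(unique(comb$bundle$residue_number[comb$bundle$atom_name == "CA"])),
               1:27)
})
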