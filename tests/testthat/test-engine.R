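test_that("the score has the stated value at the empty and perfect points", {
  atoms <- enumerate_atoms(protein_sequence("AK"))
  pri <- statistical_priors(atoms)
  ex <- expected_peaks_throughbond("N15HSQC", atoms)   # single peak (HN2,N2)
  mu_h <- pri$mean[pri$residue_number == 2 & pri$atom_name == "HN"]
  mu_n <- pri$mean[pri$residue_number == 2 & pri$atom_name == "N"]
  obs <- make_peaks("N15HSQC", cbind(mu_h, mu_n))
  p <- engine_params(lambda = 0.2, beta = 0.5)
  empty <- tibble::tibble(expected_row = integer(), spectrum = character(),
                          obs_id = integer())
  expect_equal(score_mapping(empty, ex, obs, pri, p),
               -0.2 * sum(ex$probability))
  full <- tibble::tibble(expected_row = 1L, spectrum = "N15HSQC", obs_id = 1L)
  # peak at prior means, zero deviation: p_e + beta per assigned atom
  expect_equal(score_mapping(full, ex, obs, pri, p),
               ex$probability + 0.5 * 2)
  # an out-of-tolerance mapping violates the solution invariant
  obs_bad <- make_peaks("N15HSQC", cbind(mu_h + 10, mu_n))
  expect_error(score_mapping(full, ex, obs_bad, pri, p), "candidate|tolerance")
})

test_that("run_single is deterministic, feasible, and handles empty data", {
  inst <- noiseless_instance(6, seed = 3)
  p <- engine_params(seed = 11, generations = 40, population_size = 20)
  s1 <- run_single(inst$expected, inst$observed, inst$priors, p)
  s2 <- run_single(inst$expected, inst$observed, inst$priors, p)
  expect_identical(s1$mapping, s2$mapping)
  expect_identical(s1$shifts, s2$shifts)
  expect_equal(s1$score, s2$score)
  # feasibility: re-scoring the returned mapping must not error and match
  expect_equal(score_mapping(s1, inst$expected, inst$observed, inst$priors, p),
               s1$score)
  # shifts respect the 3-sd prior range
  j <- dplyr::inner_join(s1$shifts, inst$priors,
                         by = c("residue_number", "atom_name"))
  expect_true(all(abs(j$shift - j$mean) <= 3 * j$sd + 1e-9))

  none <- inst$observed[0, ]
  s0 <- run_single(inst$expected, none, inst$priors, p)
  expect_equal(s0$n_mapped, 0L)
  expect_equal(nrow(s0$shifts), 0L)
  expect_error(run_single(inst$expected[0, ], inst$observed, inst$priors, p),
               "no expected")
})

test_that("noiseless observations are recovered exactly", {
  inst <- noiseless_instance(8, spectra = c("N15HSQC", "HNCA", "CBCAcoNH"),
                             seed = 5)
  sol <- run_single(inst$expected, inst$observed, inst$priors,
                    engine_params(seed = 2, generations = 80))
  expect_equal(sol$n_mapped, nrow(inst$expected))
  expect_shift_equal(sol, inst$truth)
})

test_that("expected peaks without priors are rejected", {
  inst <- noiseless_instance(4, seed = 6)
  pri <- inst$priors[inst$priors$atom_name != "CA", ]
  expect_error(run_single(inst$expected, inst$observed, pri, engine_params()),
               "without a prior")
})

test_that("the exhaustive oracle picks the better of two candidates", {
  atoms <- enumerate_atoms(protein_sequence("AK"))
  pri <- statistical_priors(atoms)
  ex <- expected_peaks_throughbond("N15HSQC", atoms)
  mu_h <- pri$mean[pri$residue_number == 2 & pri$atom_name == "HN"]
  mu_n <- pri$mean[pri$residue_number == 2 & pri$atom_name == "N"]
  obs <- make_peaks("N15HSQC", cbind(c(mu_h, mu_h + 0.8), c(mu_n, mu_n + 2)))
  sol <- exhaustive_search(ex, obs, pri, engine_params())
  expect_equal(sol$mapping$obs_id, 1L)
  expect_error(exhaustive_search(ex, make_peaks("N15HSQC",
    matrix(rep(c(mu_h, mu_n), 25), ncol = 2, byrow = TRUE)), pri,
    engine_params(), max_states = 10), "too large")
})

test_that("run_single never beats the exhaustive optimum on random instances", {
  set.seed(42)
  wins <- 0
  n <- 12
  for (i in seq_len(n)) {
    sq <- random_sequence(4, seed = 100 + i)
    atoms <- enumerate_atoms(sq)
    pri <- statistical_priors(atoms)
    ex <- dplyr::bind_rows(expected_peaks_throughbond("N15HSQC", atoms),
                           expected_peaks_throughbond("HNCA", atoms))
    ex <- ex[seq_len(min(6, nrow(ex))), ]
    truth <- sample_true_shifts(pri, seed = 200 + i)
    obs <- simulate_peak_lists(ex, truth,
                               noise_model(position_jitter = 1 / 3,
                                           detection = FALSE,
                                           artifact_rate = 0.3,
                                           seed = 300 + i))
    obs <- obs[seq_len(min(8, nrow(obs))), ]
    p <- engine_params(seed = i, generations = 50, population_size = 20)
    s1 <- run_single(ex, obs, pri, p)
    s2 <- exhaustive_search(ex, obs, pri, p, max_states = 3e5)
    expect_lte(s1$score, s2$score + 1e-9)
    if (s1$score >= s2$score - 1e-9) wins <- wins + 1
  }
  expect_gte(wins / n, 0.9)
})

test_that("two expected peaks may share one observed peak (overlap)", {
  # two amides with identical priors and a single observed HSQC peak:
  # the optimum maps both expected peaks onto it
  atoms <- enumerate_atoms(protein_sequence("AAA"))
  pri <- statistical_priors(atoms)
  ex <- expected_peaks_throughbond("N15HSQC", atoms)   # 2 peaks
  mu_h <- pri$mean[pri$atom_name == "HN"][1]
  mu_n <- pri$mean[pri$atom_name == "N"][1]
  obs <- make_peaks("N15HSQC", cbind(mu_h, mu_n))
  sol <- exhaustive_search(ex, obs, pri, engine_params())
  expect_equal(sol$mapping$obs_id, c(1L, 1L))
  # forcing one peak unmapped strictly reduces the attainable score
  one <- tibble::tibble(expected_row = 1L, spectrum = "N15HSQC", obs_id = 1L)
  expect_lt(score_mapping(one, ex, obs, pri, engine_params()), sol$score)
})

test_that("tidy and glance expose the solution tables", {
  inst <- noiseless_instance(5, seed = 9)
  sol <- run_single(inst$expected, inst$observed, inst$priors,
                    engine_params(seed = 1, generations = 30))
  td <- tidy(sol)
  expect_true(all(c("residue_number", "atom_name", "shift") %in% names(td)))
  gl <- glance(sol)
  expect_equal(gl$n_assigned, nrow(td))
  expect_equal(gl$score, sol$score)
})
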