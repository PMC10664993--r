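test_that("unanimous runs give full support and a strong class", {
  cons <- consensus(fake_runs(rep(4.32, 20)))
  expect_equal(cons$support, 1)
  expect_equal(cons$class, "strong")
  expect_equal(cons$shift, 4.32)
  expect_equal(cons$n_runs_found, 20L)
})

test_that("the 80% support boundary is inclusive: 16/20 strong, 15/20 weak", {
  cons16 <- consensus(fake_runs(c(rep(4.32, 16), rep(7.10, 4))))
  expect_equal(cons16$support, 0.8)
  expect_equal(cons16$class, "strong")
  expect_equal(cons16$shift, 4.32)

  cons15 <- consensus(fake_runs(c(rep(4.32, 15), rep(7.10, 5))))
  expect_equal(cons15$support, 0.75)
  expect_equal(cons15$class, "weak")
})

test_that("consensus is invariant to run order and needs R >= 2", {
  vals <- c(4.32, 4.33, 4.31, 7.1, 4.32, 4.34)
  a <- consensus(fake_runs(vals))
  b <- consensus(fake_runs(rev(vals)))
  expect_equal(a$shift, b$shift)
  expect_equal(a$support, b$support)
  expect_error(consensus(fake_runs(4.32)), "at least 2")
})

test_that("the consensus window is the max-coverage window, mean-reported", {
  # values 1.00, 1.02, 1.05 within one 0.03-halfwidth window; 2.0 apart
  cons <- consensus(fake_runs(c(1.00, 1.02, 1.04, 2.0)))
  expect_equal(cons$support, 0.75)
  expect_equal(cons$shift, mean(c(1.00, 1.02, 1.04)))
})

test_that("atoms found in few runs are demoted to weak", {
  runs <- c(fake_runs(5.5),
            rep(list(tibble::tibble(residue_number = integer(),
                                    atom_name = character(),
                                    nucleus = character(),
                                    shift = numeric())), 19))
  cons <- consensus(runs)
  expect_equal(cons$n_runs_found, 1L)
  expect_equal(cons$class, "weak")     # 100% support but sparse
})

test_that("unassigned atoms appear with class unassigned when atoms given", {
  atoms <- enumerate_atoms(protein_sequence("AG"))
  cons <- consensus(fake_runs(c(4.3, 4.3)), atom_set = atoms)
  expect_equal(nrow(cons), nrow(atoms))
  expect_true(all(cons$class[is.na(cons$shift)] == "unassigned"))
})

test_that("the accuracy estimators evaluate the printed linear forms", {
  est0 <- estimate_accuracy(0)
  expect_equal(est0$A, 7.88)
  expect_equal(est0$A_strong, 51.49)
  est100 <- estimate_accuracy(100)
  expect_equal(est100$A, 96.88)
  expect_equal(est100$A_strong, 96.49)
  est <- estimate_accuracy(c(20, 50))
  expect_equal(est$A, 0.89 * c(20, 50) + 7.88)
  expect_equal(est$A_strong, 0.45 * c(20, 50) + 51.49)
  expect_error(estimate_accuracy(-1), "0, 100")
  expect_error(estimate_accuracy(101), "0, 100")
})
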