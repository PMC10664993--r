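test_that("statistical priors pass table values through with full coverage", {
  atoms <- enumerate_atoms(protein_sequence("A", first_residue_number = 2))
  ca <- atoms[atoms$atom_name == "CA", ]
  tab <- tibble::tibble(residue_type = "ALA", atom_name = "CA",
                        mean = 53.1, sd = 2.0)
  pri <- statistical_priors(ca, tab)
  expect_equal(pri$mean, 53.1)
  expect_equal(pri$sd, 2.0)
  expect_equal(pri$source, "statistics")

  sq <- random_sequence(10, seed = 7)
  atoms10 <- enumerate_atoms(sq)
  pri10 <- statistical_priors(atoms10)
  expect_equal(nrow(pri10), nrow(atoms10))
  expect_true(all(pri10$sd > 0))
})

test_that("a missing statistics entry is reported by atom", {
  atoms <- enumerate_atoms(protein_sequence("W", first_residue_number = 3))
  tab <- default_shift_statistics()
  tab <- tab[!(tab$residue_type == "TRP" & tab$atom_name == "NE1"), ]
  expect_error(statistical_priors(atoms, tab), "NE1")
})

test_that("predicted priors overlay backbone atoms with tabulated sds", {
  sq <- random_sequence(8, seed = 5)
  atoms <- enumerate_atoms(sq)
  preds <- tibble::tibble(residue_number = c(5L, 5L),
                          atom_name = c("CA", "N"), shift = c(58.2, 119.0))
  pri <- predicted_priors(atoms, preds)
  ca <- pri[pri$residue_number == 5 & pri$atom_name == "CA", ]
  expect_equal(ca$mean, 58.2)
  expect_equal(ca$sd, 0.77)
  expect_equal(ca$source, "predicted")
  n5 <- pri[pri$residue_number == 5 & pri$atom_name == "N", ]
  expect_equal(n5$mean, 119.0)
  expect_equal(n5$sd, 1.98)
})

test_that("predicted priors reject non-backbone atoms and default to no-op", {
  atoms <- enumerate_atoms(protein_sequence("AK"))
  expect_error(predicted_priors(atoms, tibble::tibble(
    residue_number = 2L, atom_name = "HB2", shift = 1.5)), "non-backbone")
  base <- statistical_priors(atoms)
  expect_equal(predicted_priors(atoms, NULL), base)
  expect_equal(predicted_priors(atoms,
    tibble::tibble(residue_number = integer(), atom_name = character(),
                   shift = numeric())), base)
})

test_that("prediction substitution touches only the six backbone names", {
  sq <- random_sequence(12, seed = 9)
  atoms <- enumerate_atoms(sq)
  base <- statistical_priors(atoms)
  preds <- dplyr::filter(base, .data$atom_name %in% c("CA", "CB", "HN")) |>
    dplyr::transmute(residue_number = .data$residue_number,
                     atom_name = .data$atom_name, shift = .data$mean + 0.5)
  pri <- predicted_priors(atoms, preds)
  changed <- pri$mean != base$mean | pri$sd != base$sd
  expect_true(all(pri$atom_name[changed] %in%
                    c("CA", "CB", "C", "HN", "HA", "N")))
  side <- !pri$atom_name %in% c("CA", "CB", "C", "HN", "HA", "N")
  expect_equal(pri$mean[side], base$mean[side])
})

test_that("sd overrides replace the default prediction uncertainties", {
  atoms <- enumerate_atoms(protein_sequence("AK"))
  preds <- tibble::tibble(residue_number = 2L, atom_name = "CA", shift = 56)
  pri <- predicted_priors(atoms, preds, sd_overrides = c(CA = 0.5))
  expect_equal(pri$sd[pri$residue_number == 2 & pri$atom_name == "CA"], 0.5)
})
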