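test_that("max_distance is the maximum over conformers", {
  b <- make_pair_bundle(5, 3.9)
  one <- b[b$conformer == 1, ]
  expect_equal(max_distance(one, "2:HA", "3:HN"), 5)   # 3-4-5 style check
  expect_equal(max_distance(b, "2:HA", "3:HN"), 5)
  b2 <- make_pair_bundle(3.0, 3.9)
  expect_equal(max_distance(b2, "2:HA", "3:HN"), 3.9)
  expect_equal(max_distance(b2, "2:HA", "2:HA"), 0)
  expect_error(max_distance(b2, "2:HA", "9:HZ"), "missing")
})

test_that("NOESY probability tiers match the printed step function", {
  b <- make_pair_bundle(3.2, 3.9)
  ep <- expected_noesy(b, pair_atom_set(), "N15NOESY")
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$probability, 0.9)
  expect_equal(ep$atom1, "HA")
  expect_equal(ep$atom2, "N")
  expect_equal(ep$atom3, "HN")

  ep2 <- expected_noesy(make_pair_bundle(4.6, 4.9), pair_atom_set(), "N15NOESY")
  expect_equal(ep2$probability, 0.7)

  ep3 <- expected_noesy(make_pair_bundle(5.8, 6.1), pair_atom_set(), "N15NOESY")
  expect_equal(nrow(ep3), 0L)
})

test_that("the tier function agrees with a brute-force classifier on a grid", {
  brute <- function(d) {
    if (d < 4) 0.9 else if (d < 4.5) 0.8 else if (d < 5) 0.7 else
      if (d < 5.5) 0.6 else if (d < 6) 0.5 else NA_real_
  }
  grid <- seq(0.05, 7, by = 0.05)
  got <- vapply(grid, function(d) {
    ep <- expected_noesy(make_pair_bundle(d, d * 0.9), pair_atom_set(),
                         "N15NOESY")
    if (nrow(ep) == 0) NA_real_ else ep$probability
  }, 0)
  expect_equal(got, vapply(grid, brute, 0))
})

test_that("symmetric NOESY partners are both emitted, diagonal excluded", {
  sq <- protein_sequence("AAA")
  atoms <- enumerate_atoms(sq)
  b <- build_structure(sq, "helix", n_conformers = 2, seed = 4)
  ep <- expected_noesy(b, atoms, "N15NOESY")
  expect_false(any(paste(ep$res1, ep$atom1) == paste(ep$res3, ep$atom3)))
  # HN2 -> HN3 and HN3 -> HN2 both present (adjacent amides in a helix)
  sig <- paste(ep$res1, ep$atom1, ep$res3, ep$atom3)
  expect_true("2 HN 3 HN" %in% sig && "3 HN 2 HN" %in% sig)
  epc <- expected_noesy(b, atoms, "N15NOESY", collapse_symmetric = TRUE)
  sigc <- paste(epc$res1, epc$atom1, epc$res3, epc$atom3)
  expect_false("2 HN 3 HN" %in% sigc && "3 HN 2 HN" %in% sigc)
  expect_error(expected_noesy(b[0, ], atoms, "N15NOESY"), "empty")
})

test_that("bundle peaks are a subset of any single conformer's peaks", {
  sq <- random_sequence(10, seed = 6)
  atoms <- enumerate_atoms(sq)
  b <- build_structure(sq, "random", n_conformers = 4, seed = 6)
  sig <- function(ep) paste(ep$res1, ep$atom1, ep$res3, ep$atom3)
  all_b <- sig(expected_noesy(b, atoms, "N15NOESY"))
  for (cf in 1:4) {
    single <- sig(expected_noesy(b[b$conformer == cf, ], atoms, "N15NOESY"))
    expect_true(all(all_b %in% single), info = cf)
  }
})

test_that("fallback bundles are seeded, need >= 2 conformers, and give local peaks", {
  sq <- random_sequence(20, seed = 8)
  b1 <- fallback_bundle(sq, n_conformers = 8, seed = 3)
  b2 <- fallback_bundle(sq, n_conformers = 8, seed = 3)
  b3 <- fallback_bundle(sq, n_conformers = 8, seed = 4)
  expect_identical(b1, b2)
  expect_false(identical(b1$x, b3$x))
  expect_error(fallback_bundle(sq, n_conformers = 1), "at least 2")

  atoms <- enumerate_atoms(sq)
  ep <- expected_noesy(fallback_bundle(sq, n_conformers = 12, seed = 5),
                       atoms, "N15NOESY")
  expect_gt(nrow(ep), 0)
  expect_true(all(abs(ep$res1 - ep$res3) <= 1))
})

test_that("backbone RMSD is zero under rigid motion and matches arithmetic", {
  sq <- random_sequence(6, seed = 2)
  b <- build_structure(sq, "helix", n_conformers = 1, seed = 2)
  expect_equal(backbone_rmsd(b, b), 0, tolerance = 1e-6)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(b[, c("x", "y", "z")]) %*% R
  b2 <- b
  b2$x <- xyz[, 1] + 5; b2$y <- xyz[, 2] - 2; b2$z <- xyz[, 3] + 1
  expect_equal(backbone_rmsd(b, b2), 0, tolerance = 1e-6)

  # 4-atom toy with identity-optimal superposition: symmetric square
  # scaled by 2, per-atom deviation 1, hence RMSD exactly 1
  square <- function(s) tibble::tibble(
    conformer = 1L, residue_number = c(1L, 1L, 1L, 2L),
    residue_type = "ALA", atom_name = c("N", "CA", "C", "N"),
    element = c("N", "C", "C", "N"),
    x = s * c(1, -1, 0, 0), y = s * c(0, 0, 1, -1), z = 0)
  expect_equal(backbone_rmsd(square(1), square(2)), 1, tolerance = 1e-6)
  expect_error(backbone_rmsd(square(1),
                             dplyr::mutate(square(1), residue_number = 9L)),
               "common")
})

test_that("PDB bundles round-trip through MODEL records", {
  sq <- protein_sequence("AKV")
  b <- build_structure(sq, "helix", n_conformers = 3, seed = 9)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_bundle_pdb(b, f)
  b2 <- read_bundle_pdb(f)
  expect_equal(length(unique(b2$conformer)), 3L)
  expect_setequal(unique(atom_key(b2$residue_number, b2$atom_name)),
                  unique(atom_key(b$residue_number, b$atom_name)))
  m <- dplyr::inner_join(b, b2, by = c("conformer", "residue_number", "atom_name"))
  expect_lt(max(abs(m$x.x - m$x.y)), 0.001)
})

test_that("missing protons are rebuilt at sensible covalent positions", {
  sq <- protein_sequence("AKV")
  b <- build_structure(sq, "helix", n_conformers = 1, seed = 9)
  heavy <- b[b$element != "H", ]
  rebuilt <- add_protons(heavy, sq)
  expect_setequal(unique(rebuilt$atom_name), unique(b$atom_name))
  hn <- rebuilt[rebuilt$atom_name == "HN" & rebuilt$residue_number == 2, ]
  n <- rebuilt[rebuilt$atom_name == "N" & rebuilt$residue_number == 2, ]
  d <- sqrt((hn$x - n$x)^2 + (hn$y - n$y)^2 + (hn$z - n$z)^2)
  expect_lt(abs(d - 1.0), 0.1)
})
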