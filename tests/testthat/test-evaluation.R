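mk_assign <- function(res, atom, shift, class = "strong") {
  tibble::tibble(residue_number = as.integer(res), atom_name = atom,
                 nucleus = nucleus_of(atom), shift = shift, class = class,
                 residue_type = "LYS")
}

test_that("exact agreement scores 100% on every correctness metric", {
  asg <- mk_assign(1:4, c("HN", "N", "CA", "HB2"), c(8.2, 120, 56, 1.7),
                   class = c("strong", "strong", "weak", "weak"))
  ref <- asg[, c("residue_number", "atom_name", "shift")]
  rep <- compare_assignment(asg, ref)
  m <- rep$metrics
  expect_equal(m$correct_strong, 100)
  expect_equal(m$correct_weak, 100)
  expect_equal(m$correct_all, 100)
})

test_that("the 1H tolerance boundary is inclusive at 0.03 ppm", {
  ref <- tibble::tibble(residue_number = 1:2, atom_name = c("HN", "HN"),
                        shift = c(8.0, 8.0))
  asg <- mk_assign(1:2, c("HN", "HN"), c(8.03, 8.031))
  det <- compare_assignment(asg, ref)$detail
  expect_true(det$correct[1])
  expect_false(det$correct[2])
})

test_that("metric denominators follow the report definitions", {
  # 10 reference atoms; 8 assigned: 6 strong all correct, 2 weak 1 correct
  ref <- tibble::tibble(residue_number = 1:10, atom_name = "CA",
                        shift = seq(50, 59))
  asg <- mk_assign(1:8, rep("CA", 8),
                   c(seq(50, 55), 56, 99),        # weak atom 8 wrong
                   class = c(rep("strong", 6), "weak", "weak"))
  m <- compare_assignment(asg, ref)$metrics
  expect_equal(m$correct_strong, 100)
  expect_equal(m$completeness_strong, 60)
  expect_equal(m$strong, 75)
  expect_equal(m$correct_weak, 50)
  expect_equal(m$correct_all, 87.5)
})

test_that("undefined ratios are NA, never 0 or 100", {
  ref <- tibble::tibble(residue_number = 1L, atom_name = "CA", shift = 50)
  asg <- mk_assign(1, "CA", 50, class = "weak")
  m <- compare_assignment(asg, ref)$metrics
  expect_true(is.na(m$correct_strong))
  expect_true(is.na(m$completeness_strong) || m$completeness_strong == 0)
  expect_equal(m$correct_weak, 100)
  expect_error(compare_assignment(asg, ref[0, ]), "empty")
})

test_that("swapped stereo pairs count as correct unless leniency is off", {
  ref <- tibble::tibble(residue_number = c(1L, 1L),
                        atom_name = c("HB2", "HB3"), shift = c(1.5, 1.9))
  asg <- mk_assign(c(1, 1), c("HB2", "HB3"), c(1.9, 1.5))
  expect_equal(compare_assignment(asg, ref)$metrics$correct_all, 100)
  expect_equal(compare_assignment(asg, ref,
                                  stereo_leniency = FALSE)$metrics$correct_all,
               0)
})

test_that("enlarging tolerances never decreases a correctness metric", {
  withr::with_seed(4, {
    ref <- tibble::tibble(residue_number = 1:30, atom_name = "CA",
                          shift = runif(30, 50, 65))
    asg <- mk_assign(1:30, rep("CA", 30), ref$shift + rnorm(30, 0, 0.5),
                     class = sample(c("strong", "weak"), 30, TRUE))
  })
  m1 <- compare_assignment(asg, ref,
                           tolerances = c("1H" = 0.03, "13C" = 0.4,
                                          "15N" = 0.4))$metrics
  m2 <- compare_assignment(asg, ref,
                           tolerances = c("1H" = 0.06, "13C" = 0.8,
                                          "15N" = 0.8))$metrics
  for (k in c("correct_strong", "correct_weak", "correct_all")) {
    expect_gte(m2[[k]], m1[[k]])
  }
  expect_error(compare_assignment(asg, ref, tolerances = c("1H" = 0.03)),
               "tolerance")
})

test_that("amide pair accuracy requires both nuclei within tolerance", {
  ref <- tibble::tibble(residue_number = c(1L, 1L, 2L, 2L),
                        atom_name = c("HN", "N", "HN", "N"),
                        shift = c(8.0, 120, 8.5, 115))
  ok_pair <- mk_assign(c(1, 1), c("HN", "N"), c(8.02, 120.3))
  expect_equal(hn_accuracy(ok_pair, ref), 100)
  bad_h <- mk_assign(c(1, 1), c("HN", "N"), c(8.05, 120.0))
  expect_equal(hn_accuracy(bad_h, ref), 0)
  both <- dplyr::bind_rows(ok_pair, mk_assign(c(2, 2), c("HN", "N"),
                                              c(8.55, 115.2)))
  expect_equal(hn_accuracy(both, ref), 50)
  no_pairs <- mk_assign(1, "HN", 8.0)
  expect_true(is.na(hn_accuracy(no_pairs, ref)))
})

test_that("evaluation is invariant to row order and inert reference padding", {
  ref <- tibble::tibble(residue_number = 1:5, atom_name = "CA",
                        shift = seq(50, 54))
  asg <- mk_assign(1:3, rep("CA", 3), c(50, 51, 99))
  m1 <- compare_assignment(asg, ref)$metrics
  m2 <- compare_assignment(asg[c(3, 1, 2), ], ref[sample(5), ])$metrics
  expect_equal(m1$correct_all, m2$correct_all)
  # extra reference atoms change completeness only
  ref_big <- dplyr::bind_rows(ref, tibble::tibble(residue_number = 6:9,
    atom_name = "CB", shift = 30))
  m3 <- compare_assignment(asg, ref_big)$metrics
  expect_equal(m1$correct_all, m3$correct_all)
  expect_lt(m3$completeness_strong, m1$completeness_strong)
})
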