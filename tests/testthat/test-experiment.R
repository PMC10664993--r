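peak_sig <- function(ep) {
  apply(ep[, c("res1", "atom1", "res2", "atom2", "res3", "atom3")], 1,
        paste, collapse = ":")
}

test_that("HNCA on AAA yields the four hand-enumerated peaks", {
  ep <- expected_peaks_throughbond("HNCA", enumerate_atoms(protein_sequence("AAA")))
  expect_setequal(peak_sig(ep), c("2:HN:2:N:2:CA", "2:HN:2:N:1:CA",
                                  "3:HN:3:N:3:CA", "3:HN:3:N:2:CA"))
  expect_equal(sort(unique(ep$probability)), c(0.80, 0.95))
  # intra peaks carry the strong pathway probability
  intra <- ep$res1 == ep$res3
  expect_true(all(ep$probability[intra] == 0.95))
  expect_true(all(ep$probability[!intra] == 0.80))
})

test_that("amide exclusions apply: HSQC on A-P-A has a single peak", {
  ep <- expected_peaks_throughbond("N15HSQC",
                                   enumerate_atoms(protein_sequence("APA")))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$res1, 3L)
  expect_equal(ep$atom1, "HN")
})

test_that("CBCAcoNH on GG emits only the CA(i-1) peak (glycine has no CB)", {
  ep <- expected_peaks_throughbond("CBCAcoNH",
                                   enumerate_atoms(protein_sequence("GG")))
  expect_equal(peak_sig(ep), "2:HN:2:N:1:CA")
})

test_that("HNCA peak counts match a brute-force enumeration for n <= 5", {
  # independent oracle: count template instances directly from the rules
  oracle <- function(seq_str) {
    sq <- protein_sequence(seq_str)
    n <- 0
    for (i in seq_len(nrow(sq))) {
      has_amide <- i > 1 && sq$residue_type[i] != "PRO"
      if (!has_amide) next
      n <- n + 1                                   # intra CA always exists
      if (i - 1 >= 1) n <- n + 1                   # sequential CA
    }
    n
  }
  for (s in c("AG", "AGV", "LKTS", "ADKLV")) {
    ep <- expected_peaks_throughbond("HNCA",
                                     enumerate_atoms(protein_sequence(s)))
    expect_equal(nrow(ep), oracle(s), info = s)
  }
})

test_that("every expected peak references existing atoms and no forbidden HN", {
  sq <- protein_sequence("APGWLKT")
  atoms <- enumerate_atoms(sq)
  keys <- atom_key(atoms$residue_number, atoms$atom_name)
  for (sp in c("N15HSQC", "C13HSQC", "HNCA", "HNCO", "CBCANH", "CBCAcoNH",
               "HBHAcoNH", "hCcoNH", "HCCHTOCSY", "CCHTOCSY")) {
    ep <- expected_peaks_throughbond(sp, atoms)
    for (d in 1:3) {
      res <- ep[[paste0("res", d)]]; at <- ep[[paste0("atom", d)]]
      ok <- is.na(at) | atom_key(res, at) %in% keys
      expect_true(all(ok), info = sp)
    }
    expect_false(any(ep$atom1 == "HN" & ep$res1 %in% c(1L, 2L)), info = sp)
  }
})

test_that("extending the chain never removes peaks of existing residues", {
  a_small <- enumerate_atoms(protein_sequence("ADKL"))
  a_large <- enumerate_atoms(protein_sequence("ADKLVN"))
  for (sp in c("HNCA", "CBCANH", "hCcoNH")) {
    sig_small <- peak_sig(expected_peaks_throughbond(sp, a_small))
    sig_large <- peak_sig(expected_peaks_throughbond(sp, a_large))
    expect_true(all(sig_small %in% sig_large), info = sp)
  }
})

test_that("unknown spectra are rejected with the supported list", {
  expect_error(expected_peaks_throughbond("NOSUCH",
    enumerate_atoms(protein_sequence("AA"))), "supported")
})

test_that("top-K selection keeps the highest-confidence through-bond peaks", {
  pk <- make_peaks("N15HSQC", cbind(runif(10, 7, 9), runif(10, 110, 125)),
                   confidence = seq(0.1, 1.0, by = 0.1))
  kept <- select_observed_peaks(pk, expected_count = 4)
  expect_equal(sort(kept$confidence), c(0.7, 0.8, 0.9, 1.0))
  expect_equal(kept$id, sort(kept$id))     # original order preserved
  expect_equal(nrow(select_observed_peaks(pk, expected_count = 50)), 10)
  expect_error(select_observed_peaks(pk, expected_count = -1), ">= 0")
  expect_error(select_observed_peaks(pk), "expected_count")
})

test_that("confidence ties break by intensity then id", {
  pk <- make_peaks("N15HSQC", cbind(c(8, 8.1, 8.2), c(120, 121, 122)),
                   confidence = c(0.5, 0.5, 0.5),
                   intensity = c(1, 3, 1))
  kept <- select_observed_peaks(pk, expected_count = 2)
  expect_equal(kept$id, c(1L, 2L))   # id 2 wins on intensity, then id 1
})

test_that("NOESY selection applies the fixed 0.1 confidence threshold", {
  pk <- make_peaks("N15NOESY", cbind(c(1, 2, 3), c(115, 116, 117),
                                     c(8, 8.2, 8.4)),
                   confidence = c(0.05, 0.1, 0.95))
  kept <- select_observed_peaks(pk)
  expect_equal(kept$confidence, c(0.1, 0.95))
  empty <- pk[0, ]
  expect_equal(nrow(select_observed_peaks(empty)), 0)
})

test_that("the spectrum library defines tolerances by nucleus", {
  lib <- spectrum_library()
  hnca <- spectrum_definition("HNCA", lib)
  expect_equal(hnca$dims[[1]]$tolerance, c(0.03, 0.4, 0.4))
  expect_equal(hnca$kind, "through-bond")
  noe <- spectrum_definition("15N-NOESY")
  expect_equal(noe$name, "N15NOESY")
  expect_equal(noe$kind, "NOESY")
  expect_equal(spectrum_definition("CBCA(CO)NH")$name, "CBCAcoNH")
})
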