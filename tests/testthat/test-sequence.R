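test_that("sequences parse from one- and three-letter input with numbering", {
  s1 <- protein_sequence("AGFV")
  expect_equal(s1$residue_type, c("ALA", "GLY", "PHE", "VAL"))
  expect_equal(s1$residue_number, 1:4)
  s2 <- protein_sequence(c("MET", "LYS"), first_residue_number = 10)
  expect_equal(s2$residue_number, c(10L, 11L))
  expect_error(protein_sequence("AXB"), "position 2")
  expect_error(protein_sequence(""), "empty")
  expect_error(protein_sequence(character(0)), "empty")
})

test_that("sequence files round-trip (numbered) and FASTA reads", {
  sq <- protein_sequence("ADKLVNG", first_residue_number = 5)
  f <- withr::local_tempfile(fileext = ".seq")
  write_sequence_numbered(sq, f)
  expect_equal(read_sequence_numbered(f), sq)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">toy protein", "ADKLV", "NG"), fa)
  expect_equal(read_sequence_fasta(fa)$residue_type, sq$residue_type)
})

test_that("glycine in chain context contributes its full atom complement", {
  # fragment numbering starting at 2 marks a non-terminal context
  atoms <- enumerate_atoms(protein_sequence("G", first_residue_number = 2))
  expect_setequal(atoms$atom_name, c("HN", "N", "CA", "HA2", "HA3", "C"))
  expect_equal(atoms$nucleus[atoms$atom_name == "N"], "15N")
  expect_equal(atoms$nucleus[atoms$atom_name == "CA"], "13C")
})

test_that("chain start and prolines carry no amide proton", {
  atoms <- enumerate_atoms(protein_sequence("APA"))
  expect_false("HN" %in% atoms$atom_name[atoms$residue_number == 1])
  r2 <- atoms[atoms$residue_number == 2, ]
  expect_false("HN" %in% r2$atom_name)
  expect_false(any(r2$element == "H" & !is.na(r2$parent) &
                     substr(r2$parent, 1, 1) == "N"))
  expect_true("HN" %in% atoms$atom_name[atoms$residue_number == 3])
})

test_that("atom enumeration is pure and consistent with the topology", {
  sq <- random_sequence(15, seed = 3)
  a1 <- enumerate_atoms(sq)
  a2 <- enumerate_atoms(sq)
  expect_identical(a1, a2)
  topo <- residue_topology()
  ok <- dplyr::semi_join(a1, topo, by = c("residue_type", "atom_name"))
  expect_equal(nrow(ok), nrow(a1))
  expect_true(all(a1$nucleus %in% c("1H", "13C", "15N")))
})
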