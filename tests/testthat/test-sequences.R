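kj12b <- kj12_cdds()$Kj12B

test_that("beta3 register extraction matches the documented numbering", {
  reg <- beta3_register(kj12b)
  expect_equal(reg$position, -5:-1)
  expect_equal(reg$aa, c("L", "R", "G", "E", "I"))
  expect_equal(reg$residue_number, 1564:1568)

  rega <- beta3_register(kj12_cdds()$Kj12A_peptide)
  expect_equal(rega$aa[c(1, 3, 5)], c("L", "G", "I"))  # -4 letter not asserted

  # k equal to the sequence length returns the whole peptide
  pent <- dd_seq("LRGEI", "pent", "CDD")
  expect_equal(beta3_register(pent, 5)$aa, c("L", "R", "G", "E", "I"))

  expect_error(beta3_register(pent, 6), class = "nrpsdock_length_error")
  expect_error(beta3_register(dd_seq("A", "x", "NDD")),
               class = "nrpsdock_role_error")
})

test_that("truncation keeps the C-terminus and renumbers", {
  short <- truncate_cdd(kj12b, 8)
  expect_equal(short$sequence, "QEYLRGEI")
  expect_equal(short$offset, 1561)
  expect_equal(residue_numbers(short), 1561:1568)

  expect_equal(truncate_cdd(kj12b, length(kj12b))$sequence, kj12b$sequence)
  expect_equal(truncate_cdd(kj12b, 5)$sequence, "LRGEI")
  expect_equal(truncate_cdd(kj12b, 5)$offset, 1564)
  expect_error(truncate_cdd(kj12b, 99), class = "nrpsdock_length_error")

  # register of the full CDD equals the 5-residue truncation
  expect_equal(beta3_register(kj12b)$aa,
               strsplit(truncate_cdd(kj12b, 5)$sequence, "")[[1]])
})

test_that("mutations apply through parent numbering with strict checking", {
  mut <- apply_mutations(kj12b, "R1565E")
  expect_equal(substr(mut$sequence, 20, 24), "LEGEI")
  expect_equal(beta3_register(mut)$aa[2], "E")

  expect_equal(apply_mutations(kj12b, parse_mutations(character(0)))$sequence,
               kj12b$sequence)

  short <- truncate_cdd(kj12b, 8)
  expect_equal(apply_mutations(short, "L1564A")$sequence, "QEYARGEI")

  expect_error(apply_mutations(kj12b, "R1500E"),
               class = "nrpsdock_range_error")
  expect_error(apply_mutations(kj12b, "K1565E"),
               class = "nrpsdock_reference_mismatch")
  expect_warning(lenient <- apply_mutations(kj12b, "K1565E", strict = FALSE),
                 "mismatch")
  expect_equal(beta3_register(lenient)$aa[2], "E")
})

test_that("mutation application is idempotent and invertible", {
  m1 <- apply_mutations(kj12b, "R1565E")
  m2 <- suppressWarnings(apply_mutations(m1, "R1565E", strict = FALSE))
  expect_equal(m1$sequence, m2$sequence)
  back <- apply_mutations(m1, "E1565R")
  expect_equal(back$sequence, kj12b$sequence)
})

test_that("monoisotopic masses reproduce reference values", {
  # the worked synthesis example: QEYARGEI as the doubly protonated ion
  expect_equal(monoisotopic_mz("QEYARGEI", 2), 483.2380, tolerance = 1e-7)
  # glycine: residue mass + water + one proton
  expect_equal(monoisotopic_mz("G", 1), 76.0393, tolerance = 1e-4)
  # additivity: GG - G difference is one glycine residue mass
  expect_equal(monoisotopic_mass("GG") - monoisotopic_mass("G"), 57.02146)
  expect_error(monoisotopic_mz("GBX", 1), class = "nrpsdock_alphabet_error")
  expect_error(monoisotopic_mz("G", 0), class = "nrpsdock_value_error")
})

test_that("m/z decreases with charge and neutral mass is order-invariant", {
  pep <- "QEYLRGEI"
  mz <- vapply(1:4, function(z) monoisotopic_mz(pep, z), 0)
  expect_true(all(diff(mz) < 0))
  expect_equal(monoisotopic_mass("QEYLRGEI"), monoisotopic_mass("IEGRLYEQ"))
})

test_that("percent identity behaves under the fixed scoring", {
  expect_equal(percent_identity("QEYLRGEI", "QEYLRGEI"), 100)
  expect_equal(percent_identity("AAAA", "AAAT"), 75)
  # symmetry over random pairs
  set.seed(7)
  for (i in 1:5) {
    a <- paste(sample(c("A", "R", "G", "E", "L"), 12, TRUE), collapse = "")
    b <- paste(sample(c("A", "R", "G", "E", "L"), 10, TRUE), collapse = "")
    expect_equal(percent_identity(a, b), percent_identity(b, a))
    if (a != b) expect_lt(percent_identity(a, b), 100)
  }
  expect_error(percent_identity("", "A"), class = "nrpsdock_value_error")
})

test_that("FASTA round trip preserves role and numbering", {
  path <- withr::local_tempfile(fileext = ".fasta")
  write_dd_fasta(kj12_cdds(), path)
  back <- read_dd_fasta(path)
  expect_equal(back$`Kj12B-CDD`$sequence, kj12b$sequence)
  expect_equal(back$`Kj12B-CDD`$offset, 1545)
  expect_equal(back$`Kj12B-CDD`$role, "CDD")
  expect_error(read_dd_fasta("no/such/file.fasta"),
               class = "nrpsdock_io_error")
})

test_that("bundled fixture FASTA matches the in-code fixtures", {
  path <- system.file("extdata", "kj12_cdds.fasta", package = "nrpsdock")
  seqs <- read_dd_fasta(path)
  expect_equal(seqs$`Kj12B-CDD`$sequence, kj12_cdds()$Kj12B$sequence)
  expect_equal(seqs$`Kj12B-CDD_short`$sequence, "QEYLRGEI")
  expect_equal(seqs$`Kj12B-CDD_short`$offset, 1561)
})
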