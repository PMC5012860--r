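# Elemental-formula arithmetic, modification masses, peptides, digestion.

test_that("parse_formula reads Hill strings and rejects malformed input", {
  expect_equal(unclass(parse_formula("C3H4O")),
               c(C = 3L, H = 4L, O = 1L), ignore_attr = TRUE)
  expect_equal(unclass(parse_formula("C622H1040N196O172S3")),
               c(C = 622L, H = 1040L, N = 196L, O = 172L, S = 3L),
               ignore_attr = TRUE)
  # underscore/subscript separators normalize to the same formula
  expect_identical(parse_formula("C_622_H_1040_N_196_O_172_S_3"),
                   parse_formula("C622H1040N196O172S3"))
  expect_error(parse_formula("C3Hx"), "Hx")
  expect_error(parse_formula("C0H2"), "zero")
  expect_error(parse_formula("C03"), "zero")
  expect_identical(length(parse_formula("")), 0L)
})

test_that("average_mass reproduces printed ligation-product masses", {
  # three printed theoretical masses of the semisynthetic H3 products
  expect_equal(round(average_mass(parse_formula("C622H1040N196O172S3")), 2),
               14112.54, tolerance = 0.011)
  expect_equal(round(average_mass(parse_formula("C670H1129N215O186S3")), 2),
               15268.90, tolerance = 0.011)
  expect_equal(round(average_mass(parse_formula("C670H1129N215O186S2")), 2),
               15236.84, tolerance = 0.011)
  expect_equal(average_mass(parse_formula("H2O")), 18.015,
               tolerance = 1e-10)
  expect_identical(average_mass(elemental_formula()), 0.0)
})

test_that("monoisotopic_mass matches printed search deltas", {
  expect_equal(monoisotopic_mass(parse_formula("CH2")), 14.01565,
               tolerance = 1e-4)
  expect_equal(monoisotopic_mass(parse_formula("C3H4O")), 56.026215,
               tolerance = 1e-4)
  expect_identical(monoisotopic_mass(elemental_formula()), 0.0)
  expect_error(monoisotopic_mass(c(Xx = 1)), "unknown element")
})

test_that("mass functions are additive over formula addition", {
  set.seed(7)
  els <- atomic_masses()$element
  for (i in 1:25) {
    f1 <- elemental_formula(stats::setNames(sample(0:9, 6, TRUE), els))
    f2 <- elemental_formula(stats::setNames(sample(0:9, 6, TRUE), els))
    expect_equal(average_mass(f1) + average_mass(f2),
                 average_mass(f1 + f2), tolerance = 1e-12)
    expect_equal(monoisotopic_mass(f1) + monoisotopic_mass(f2),
                 monoisotopic_mass(f1 + f2), tolerance = 1e-12)
  }
})

test_that("adjusted_mod_mass reproduces the four printed adjusted deltas", {
  tab <- mod_table()
  expect_equal(adjusted_mod_mass(tab$ub, "propionylated"), 58.016716,
               tolerance = 1e-4)
  expect_equal(adjusted_mod_mass(tab$me2, "propionylated"), -27.994915,
               tolerance = 1e-4)
  expect_equal(adjusted_mod_mass(tab$me3, "propionylated"), -13.979264,
               tolerance = 1e-4)
  expect_equal(adjusted_mod_mass(tab$ac, "propionylated"), -14.015644,
               tolerance = 1e-4)
})

test_that("mono-methylation and non-lysine mods are exempt from adjustment", {
  tab <- mod_table()
  expect_equal(adjusted_mod_mass(tab$me, "propionylated"), 14.01565,
               tolerance = 1e-4)
  expect_equal(adjusted_mod_mass(tab$ox, "propionylated"), 15.99492,
               tolerance = 1e-4)
  expect_equal(adjusted_mod_mass(tab$ph, "propionylated"), 79.966331,
               tolerance = 1e-4)
  # underivatized scheme leaves every delta at its composition mass
  expect_equal(adjusted_mod_mass(tab$ub, "underivatized"), 114.042931,
               tolerance = 1e-4)
  expect_equal(adjusted_mod_mass(tab$ac, "underivatized"), 42.010571,
               tolerance = 1e-4)
})

test_that("adjustment + propionyl recovers the unadjusted delta exactly", {
  tab <- mod_table()
  for (m in c("ub", "me2", "me3", "ac")) {
    expect_equal(adjusted_mod_mass(tab[[m]], "propionylated") +
                   monoisotopic_mass(parse_formula("C3H4O")),
                 monoisotopic_mass(tab[[m]]$composition),
                 tolerance = 1e-9)
  }
})

test_that("peptide_mass agrees with brute-force residue sums", {
  # independent residue table for the brute force (Expasy values)
  ref <- c(A = 71.03711, R = 156.10111, T = 101.04768, K = 128.09496,
           G = 57.02146)
  water <- 18.0105646863
  g <- modified_peptide("G", scheme = "underivatized")
  expect_equal(peptide_mass(g), ref[["G"]] + water, tolerance = 1e-4)

  bare <- modified_peptide("ARTK")
  unprop <- modified_peptide("ARTK", scheme = "underivatized")
  # static propionyl on the single lysine only (N-terminal prop off)
  expect_equal(peptide_mass(bare, nterm_prop = FALSE),
               peptide_mass(unprop) + 56.026215, tolerance = 1e-4)
  # N-terminal propionyl adds exactly one more
  expect_equal(peptide_mass(bare, nterm_prop = TRUE) -
                 peptide_mass(bare, nterm_prop = FALSE),
               56.026215, tolerance = 1e-4)

  # two-route equality: static prop + adjusted GlyGly == full GlyGly
  ub <- modified_peptide("ARTK", c("4" = "ub"))
  expect_equal(peptide_mass(ub, nterm_prop = FALSE),
               peptide_mass(unprop) + 114.042931, tolerance = 1e-4)
  expect_error(modified_peptide("ARTZ"), "unknown residue")
})

test_that("two-route equality holds for every adjusted lysine state", {
  unprop_base <- peptide_mass(modified_peptide("ARTKQTAR",
                                               scheme = "underivatized"))
  for (m in c("ub", "me2", "me3", "ac")) {
    p <- modified_peptide("ARTKQTAR", stats::setNames(m, "4"))
    full <- monoisotopic_mass(mod_table()[[m]]$composition)
    expect_equal(peptide_mass(p, nterm_prop = FALSE),
                 unprop_base + full, tolerance = 1e-9)
  }
})

test_that("validate_candidate enforces length, caps, and the total cap", {
  params <- search_params()
  expect_false(validate_candidate(modified_peptide("ARTKG"), params)$accept)
  expect_match(validate_candidate(modified_peptide("ARTKG"),
                                  params)$reason, "length")
  long <- modified_peptide(strrep("A", 26))
  expect_match(validate_candidate(long, params)$reason, "length")
  ok <- modified_peptide("KQLATKAAR", c("1" = "ub", "6" = "ub"))
  expect_true(validate_candidate(ok, params)$accept)
  three_ub <- modified_peptide("KSTGGKAPKR",
                               c("1" = "ub", "6" = "ub", "9" = "ub"))
  expect_match(validate_candidate(three_ub, params)$reason, "cap")
  five <- modified_peptide("MKSKGGKASK",
                           c("1" = "ox", "2" = "ub", "4" = "ub",
                             "7" = "ac", "10" = "ac"))
  expect_match(validate_candidate(five, params)$reason, "total")
})

test_that("digest applies the Arg-C and trypsin rules", {
  expect_identical(digest("ARGR", "ArgC", 0)$peptide, c("AR", "GR"))
  expect_identical(digest("AKPR", "trypsin", 0)$peptide, "AKPR")
  expect_identical(digest("AAAA", "ArgC", 0)$peptide, "AAAA")
  expect_identical(digest("AKGR", "trypsin", 0)$peptide, c("AK", "GR"))
  expect_error(digest("ARGR", "ArgC", -1), "max_missed")
  # missed cleavages enumerate every fully enzymatic window
  d <- digest("ARGRK", "ArgC", 1)
  expect_setequal(d$peptide, c("AR", "GR", "K", "ARGR", "GRK"))
  expect_identical(sort(unique(d$missed)), 0:1)
})

test_that("the shipped modification table file matches the built-ins and
           is user-extensible", {
  shipped <- read_mod_table()
  builtin <- mod_table()
  expect_identical(names(shipped), names(builtin))
  for (m in names(builtin)) {
    expect_equal(shipped[[m]], builtin[[m]], label = m)
  }
  # user extension: add a custom modification
  path <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(name = "succ", targets = "K", composition = "C4H4O3",
               max_count = 2, methylation_class = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  custom <- read_mod_table(path)
  expect_equal(monoisotopic_mass(custom$succ$composition), 100.01604,
               tolerance = 1e-4)  # succinylation, Unimod
})

test_that("read_fasta preserves multi-record sequences and descriptions", {
  skip_if_not_installed("Biostrings")
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">histone H3 tail", "ARTKQTARKSTGGKAPR", "KQLATKAAR",
               ">ubiquitin fragment", "MQIFVK"), path)
  seqs <- read_fasta(path)
  expect_identical(unname(seqs),
                   c("ARTKQTARKSTGGKAPRKQLATKAAR", "MQIFVK"))
  expect_identical(names(seqs), c("histone H3 tail",
                                  "ubiquitin fragment"))
})

test_that("zero-missed digest concatenates back to the protein", {
  set.seed(11)
  aas <- names(histoneub:::residue_masses())
  for (i in 1:20) {
    prot <- paste0(sample(aas, sample(10:60, 1), TRUE), collapse = "")
    for (enz in c("ArgC", "trypsin")) {
      d <- digest(prot, enz, 0)
      expect_identical(paste0(d$peptide, collapse = ""), prot)
    }
  }
})
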