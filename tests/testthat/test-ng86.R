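test_that("site counts match single-nucleotide-neighbor enumeration", {
  # spot values forced by the code table
  expect_equal(ng86_count_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng86_count_sites("ATG"), c(s = 0, n = 3))
  # full table against the brute-force oracle
  for (cod in oracle_sense_codons()) {
    expect_equal(ng86_count_sites(cod), oracle_count_sites(cod),
                 info = cod)
  }
  expect_error(ng86_count_sites("TAA"), "sense codon")
  expect_error(ng86_count_sites("ANA"), "sense codon")
})

test_that("difference counts follow pathway averaging with stop exclusion", {
  expect_equal(ng86_count_differences("TTT", "TTA"), c(sd = 0, nd = 1))
  expect_equal(ng86_count_differences("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
  expect_equal(ng86_count_differences("AAA", "AAA"), c(sd = 0, nd = 0))
  # symmetry and Hamming-sum identity on random codon pairs
  a <- random_sense_codons(300, seed = 21)
  b <- random_sense_codons(300, seed = 22)
  for (i in seq_along(a)) {
    d_ab <- suppressWarnings(ng86_count_differences(a[i], b[i]))
    d_ba <- suppressWarnings(ng86_count_differences(b[i], a[i]))
    expect_equal(d_ab, d_ba, info = paste(a[i], b[i]))
    hd <- sum(strsplit(a[i], "")[[1]] != strsplit(b[i], "")[[1]])
    expect_equal(unname(sum(d_ab)), hd, info = paste(a[i], b[i]))
  }
})

test_that("estimate handles degenerate and boundary inputs", {
  cod <- random_sense_codons(200, seed = 31)
  same <- gapless_ca(cod, cod)
  e <- ng86_estimate(same)
  expect_equal(e$dS, 0)
  expect_equal(e$dN, 0)
  expect_equal(e$omega, 999)           # dS = 0 sentinel, always filtered
  expect_error(ng86_estimate(gapless_ca(character(0), character(0))),
               "empty")
  # a purely synonymous contrast gives omega exactly 0
  ca <- gapless_ca(c("TTT", "GGA", "CCC"), c("TTC", "GGG", "CCT"))
  e2 <- ng86_estimate(ca)
  expect_equal(e2$Nd, 0)
  expect_equal(e2$omega, 0)
})

test_that("estimator is symmetric in the two sequences", {
  a <- random_sense_codons(500, seed = 41)
  b <- random_sense_codons(500, seed = 42)
  keep <- suppressWarnings({
    e1 <- ng86_estimate(gapless_ca(a, b))
    e2 <- ng86_estimate(gapless_ca(b, a))
  })
  expect_equal(e1$S, e2$S)
  expect_equal(e1$Sd, e2$Sd)
  expect_equal(e1$dS, e2$dS)
  expect_equal(e1$omega, e2$omega)
})

test_that("omega is recovered on a long simulated alignment", {
  Q <- build_codon_rate_matrix(kappa = 1, omega = 0.2, "uniform")
  set.seed(55)
  mach <- omegapair:::codon_machinery("11")
  anc <- sample(mach$sense, 10000, replace = TRUE)
  a <- evolve_codon_sequence(anc, 0.15, Q)
  b <- evolve_codon_sequence(anc, 0.15, Q)
  e <- ng86_estimate(gapless_ca(a, b))
  expect_gt(e$omega, 0.17)
  expect_lt(e$omega, 0.23)
})
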