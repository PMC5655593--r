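test_that("the rate matrix is a scaled reversible GY94 generator", {
  Q <- build_codon_rate_matrix(kappa = 2, omega = 0.3, "uniform")
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  pi61 <- attr(Q, "pi")
  # detailed balance (time reversibility)
  expect_lt(max(abs(pi61 * Q - t(pi61 * t(Q)))), 1e-12)
  # unit substitution rate at stationarity
  expect_equal(-sum(pi61 * diag(Q)), 1, tolerance = 1e-12)
  # omega = 0 kills every nonsynonymous rate
  Q0 <- build_codon_rate_matrix(kappa = 2, omega = 0, "uniform")
  mach <- omegapair:::codon_machinery("11")
  nonsyn <- mach$nb[!mach$nb$syn, ]
  expect_true(all(Q0[cbind(nonsyn$from, nonsyn$to)] == 0))
  expect_error(build_codon_rate_matrix(2, 0.3, rep(c(0, 1), c(1, 60))),
               "positive")
})

test_that("sequence evolution is seed-deterministic and t = 0 is identity", {
  Q <- build_codon_rate_matrix(kappa = 1, omega = 1, "uniform")
  anc <- random_sense_codons(500, seed = 301)
  expect_identical(evolve_codon_sequence(anc, 0, Q, seed = 1), anc)
  d1 <- evolve_codon_sequence(anc, 0.4, Q, seed = 7)
  d2 <- evolve_codon_sequence(anc, 0.4, Q, seed = 7)
  expect_identical(d1, d2)
  d3 <- evolve_codon_sequence(anc, 0.4, Q, seed = 8)
  expect_false(identical(d1, d3))
})

test_that("the realized codon change proportion matches the kernel", {
  Q <- build_codon_rate_matrix(kappa = 1, omega = 1, "uniform")
  pi61 <- attr(Q, "pi")
  P <- omegapair:::.transition_matrix(Q, 0.5)
  p_change <- 1 - sum(pi61 * diag(P))
  set.seed(303)
  mach <- omegapair:::codon_machinery("11")
  anc <- sample(mach$sense, 10000, replace = TRUE)
  desc <- evolve_codon_sequence(anc, 0.5, Q)
  obs <- mean(anc != desc)
  se <- sqrt(p_change * (1 - p_change) / 10000)
  expect_lt(abs(obs - p_change), 3 * se)
})

test_that("evolution preserves the stationary codon distribution", {
  Q <- build_codon_rate_matrix(kappa = 2, omega = 0.5, "uniform")
  set.seed(307)
  mach <- omegapair:::codon_machinery("11")
  anc <- sample(mach$sense, 20000, replace = TRUE)
  desc <- evolve_codon_sequence(anc, 1.0, Q)
  freq <- table(factor(desc, levels = mach$sense)) / length(desc)
  # chi-square comparison against uniform stays unremarkable
  chisq <- sum((as.numeric(freq) - 1 / 61)^2 / (1 / 61)) * length(desc)
  expect_lt(chisq, qchisq(0.999, df = 60))
})

test_that("simulated genome pairs honor the requested noncoding fraction", {
  sp <- simulate_genome_pair(sim_config(
    n_genes = 40, gene_len_codons = 100, noncoding_fraction = 0.25,
    seed = 311))
  expect_lt(abs(coding_density(sp$genome_a) - 75), 1)
  expect_lt(abs(coding_density(sp$genome_b) - 75), 1)
  expect_lt(abs(100 * (1 - sp$truth$noncoding_fraction) -
                  coding_density(sp$genome_a)), 1e-9)
  # annotations line up gene for gene
  expect_identical(sp$genome_a$cds$gene_id, sp$genome_b$cds$gene_id)
  expect_equal(nrow(sp$genome_a$skipped), 0L)
})

test_that("a zero-divergence pair is entirely removed by the dS filter", {
  sp <- simulate_genome_pair(sim_config(
    n_genes = 15, gene_len_codons = 80, t = 0, noncoding_fraction = 0.1,
    seed = 313))
  res <- suppressMessages(run_pair_analysis(
    sp$genome_a, sp$genome_b, pipeline_config(compute_ani = FALSE)))
  expect_equal(res$summary$n_retained, 0L)
  expect_false(res$summary$keep)
  expect_true(all(res$orthologs$reason == "dS < 0.1"))
})

test_that("cohort simulation encodes the regime directions in its truth", {
  coh <- simulate_cohort("archaeal_like", n_pairs = 8, seed = 317,
                         n_genes_range = c(30, 70), gene_len_codons = 90)
  expect_equal(length(coh$pairs), 8L)
  expect_gt(cor(coh$manifest$n_genes, coh$manifest$omega_true,
                method = "spearman"), 0)
  expect_gt(cor(coh$manifest$n_genes, coh$manifest$noncoding_fraction,
                method = "spearman"), 0)
  cob <- simulate_cohort("bacterial_like", n_pairs = 8, seed = 317,
                         n_genes_range = c(30, 70), gene_len_codons = 90)
  expect_lt(cor(cob$manifest$n_genes, cob$manifest$omega_true,
                method = "spearman"), 0)
})

test_that("identical seeds give byte-identical cohort files", {
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  simulate_cohort("bacterial_like", n_pairs = 5, seed = 331,
                  n_genes_range = c(20, 40), gene_len_codons = 60,
                  outdir = td1)
  simulate_cohort("bacterial_like", n_pairs = 5, seed = 331,
                  n_genes_range = c(20, 40), gene_len_codons = 60,
                  outdir = td2)
  for (f in list.files(td1)) {
    expect_identical(readBin(file.path(td1, f), "raw", 2e6),
                     readBin(file.path(td2, f), "raw", 2e6), label = f)
  }
})
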