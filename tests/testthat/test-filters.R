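fake_estimate <- function(dS, omega, gene = "g") {
  omegapair:::new_dnds_estimate(gene, gene, "NG86", S = 100, N = 200,
                                Sd = 10, Nd = 10, dS = dS,
                                dN = if (dS == 0) 0 else omega * dS,
                                kappa = 1, converged = TRUE)
}

test_that("saturation filters discard strictly outside the stated bounds", {
  flt <- apply_saturation_filters(list(
    fake_estimate(0.05, 0.3, "low"),
    fake_estimate(0.5, 0.2, "ok"),
    fake_estimate(0.8, 100, "high_omega"),
    fake_estimate(2.0, 0.2, "saturated")))
  expect_equal(flt$retained$gene_a, "ok")
  expect_equal(flt$discarded$reason[flt$discarded$gene_a == "low"], "dS < 0.1")
  expect_equal(flt$discarded$reason[flt$discarded$gene_a == "high_omega"],
               "dN/dS > 99")
  expect_equal(flt$discarded$reason[flt$discarded$gene_a == "saturated"],
               "dS > 1.6")
  # sentinels always land in a discard bucket
  sent <- apply_saturation_filters(list(fake_estimate(0, 999, "ident"),
                                        fake_estimate(Inf, 0, "sat")))
  expect_equal(nrow(sent$retained), 0L)
})

test_that("the retained set does not depend on input order", {
  ests <- list(fake_estimate(0.05, 0.3, "e1"), fake_estimate(0.5, 0.2, "e2"),
               fake_estimate(1.7, 0.1, "e3"), fake_estimate(1.2, 0.4, "e4"))
  f1 <- apply_saturation_filters(ests)
  f2 <- apply_saturation_filters(rev(ests))
  expect_setequal(f1$retained$gene_a, f2$retained$gene_a)
  expect_setequal(paste(f1$discarded$gene_a, f1$discarded$reason),
                  paste(f2$discarded$gene_a, f2$discarded$reason))
})

test_that("the 5% retention rule is inclusive and SEM needs two values", {
  retained <- function(omegas) {
    dnds <- lapply(seq_along(omegas), function(i) {
      fake_estimate(0.5, omegas[i], sprintf("g%03d", i))
    })
    apply_saturation_filters(dnds)$retained
  }
  # genomes with 2,000 and 2,200 CDS: average capacity 2,100, threshold 105
  s104 <- summarize_genome_pair(retained(rep(0.2, 104)), 104, 2000, 2200)
  s105 <- summarize_genome_pair(retained(rep(0.2, 105)), 105, 2000, 2200)
  expect_false(s104$keep)
  expect_true(s105$keep)
  expect_equal(s105$retained_fraction_of_capacity, 0.05)
  # closed-form mean and SEM
  s3 <- summarize_genome_pair(retained(c(0.1, 0.2, 0.3)), 3, 30, 30)
  expect_equal(s3$mean_omega, 0.2)
  expect_equal(s3$sem_omega, 0.1 / sqrt(3))
  # fewer than two retained: SEM missing, keep forced off
  s1 <- summarize_genome_pair(retained(0.2), 1, 10, 10)
  expect_true(is.na(s1$sem_omega))
  expect_false(s1$keep)
  s0 <- summarize_genome_pair(retained(numeric(0)), 0, 10, 10)
  expect_true(is.na(s0$mean_omega))
  expect_false(s0$keep)
})
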