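test_that("spearman handles monotone data, ties and exact P values", {
  r1 <- spearman(c(1, 2, 3, 4), c(1, 4, 9, 16))
  expect_equal(r1$rs, 1)
  r2 <- spearman(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r2$rs, -1)
  expect_equal(r2$p_two_sided, 2 / 6)   # enumeration over 3! permutations
  expect_equal(r2$method, "exact-permutation")
  # midranks for ties: rank correlation equals Pearson on midranks
  x <- c(1, 2, 3, 4); y <- c(5, 2, 2, 1)
  r3 <- spearman(x, y)
  expect_equal(r3$rs, stats::cor(rank(x), rank(y)))
  expect_error(spearman(1:2, 2:1), "at least 3")
  expect_error(spearman(1:4, rep(1, 4)), "zero variance")
  expect_error(spearman(c(1, 2, NA), c(1, 2, 3)), "missing")
})

test_that("exact P values match cor.test enumeration for n <= 9", {
  set.seed(17)
  for (n in c(4, 5, 6, 7)) {
    for (rep in 1:4) {
      x <- sample(100, n); y <- sample(100, n)
      ours <- spearman(x, y)
      ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                              exact = TRUE))
      expect_equal(ours$rs, unname(ref$estimate), tolerance = 1e-12)
      expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-10,
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("t-approximation is used above n = 9 and degenerates to exact at |rs| = 1", {
  set.seed(19)
  x <- rnorm(20); y <- x + rnorm(20, sd = 2)
  ours <- spearman(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  expect_equal(ours$method, "t-approximation")
  expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-10)
  mono <- spearman(1:12, (1:12)^3)
  expect_equal(mono$rs, 1)
  expect_equal(mono$p_two_sided, 2 / factorial(12))
})

test_that("spearman is symmetric and invariant to monotone transforms", {
  set.seed(23)
  x <- rnorm(15); y <- rnorm(15)
  a <- spearman(x, y); b <- spearman(y, x)
  expect_equal(a$rs, b$rs)
  expect_equal(a$p_two_sided, b$p_two_sided)
  tr <- spearman(exp(x), y)
  expect_equal(a$rs, tr$rs)
  expect_equal(a$p_two_sided, tr$p_two_sided)
})

test_that("sem equals the closed form and rejects tiny samples", {
  expect_equal(sem(c(0.1, 0.2, 0.3)), 0.1 / sqrt(3))
  expect_equal(sem(rep(2, 5)), 0)
  set.seed(29)
  v <- rnorm(40)
  expect_equal(sem(v), sqrt(sum((v - mean(v))^2) / 39) / sqrt(40))
  expect_error(sem(1), "at least 2")
})
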