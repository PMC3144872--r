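test_that("allelic chi-square matches the closed form and worked example", {
  res <- chi2_allelic(c(60, 40), c(40, 60))
  expect_equal(res$statistic, 8.0, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(8, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$p_value, 4.677735e-3, tolerance = 1e-6)

  same <- chi2_allelic(c(50, 50), c(50, 50))
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
})

test_that("chi-square agrees with the reference implementation to 1e-10", {
  set.seed(11)
  for (i in 1:200) {
    tab <- matrix(sample.int(200, 4, replace = TRUE), 2)
    res <- chi2_allelic(tab[1, ], tab[2, ])
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("chi-square is invariant under swapping rows or columns", {
  set.seed(12)
  for (i in 1:25) {
    a <- sample.int(100, 2)
    b <- sample.int(100, 2)
    s <- chi2_allelic(a, b)$statistic
    expect_equal(chi2_allelic(b, a)$statistic, s, tolerance = 1e-12)
    expect_equal(chi2_allelic(rev(a), rev(b))$statistic, s,
                 tolerance = 1e-12)
  }
})

test_that("degenerate 2x2 tables are rejected", {
  expect_error(chi2_allelic(c(0, 0), c(10, 10)), "degenerate")
  expect_error(chi2_allelic(c(0, 10), c(0, 10)), "degenerate")
  expect_error(chi2_allelic(c(-1, 10), c(5, 5)), "non-negative")
})

test_that("pool t-test matches the hand-computed Welch formula", {
  x <- c(0.60, 0.62, 0.58, 0.61)
  y <- c(0.50, 0.49, 0.52, 0.51)
  res <- pool_ttest(x, y)
  # textbook Welch-Satterthwaite, written out independently
  se2 <- var(x) / 4 + var(y) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df_hand),
               tolerance = 1e-10)

  ref <- t.test(x, y)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)

  pooled <- pool_ttest(x, y, var_equal = TRUE)
  ref2 <- t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$statistic, unname(ref2$statistic), tolerance = 1e-10)
  expect_equal(pooled$df, 6)
  expect_equal(pooled$p_value, ref2$p.value, tolerance = 1e-10)
})

test_that("pool t-test handles ties, symmetry and preconditions", {
  z <- c(0.50, 0.52, 0.48)
  res <- pool_ttest(z, z)
  expect_identical(res$statistic, 0)
  expect_identical(res$p_value, 1)

  set.seed(13)
  for (i in 1:20) {
    x <- runif(4, 0.3, 0.7)
    y <- runif(5, 0.3, 0.7)
    expect_equal(pool_ttest(x, y)$p_value, pool_ttest(y, x)$p_value,
                 tolerance = 1e-12)
  }
  expect_error(pool_ttest(c(0.5, 0.5), 0.5), "insufficient pools")
  expect_error(pool_ttest(c(0.5, 0.5), c(0.4, 0.4)), "degenerate variance")
  expect_error(pool_ttest(c(0.5, 1.2), c(0.4, 0.5)), "\\[0, 1\\]")
})

test_that("QC filters drop low-MAF and high-missingness markers", {
  snps <- data.frame(
    chr = "1", snp = paste0("rs", 1:6), bp = 1:6 * 1000,
    maf = c(0.005, 0.30, 0.008, 0.25, 0.004, 0.40),
    f_miss = c(0.01, 0.10, 0.02, 0.01, 0.20, 0.00))
  res <- filter_snps(snps, maf_min = 0.01, missing_max = 0.05)
  expect_equal(nrow(res$retained), 2)
  expect_equal(nrow(res$excluded), 4)
  expect_setequal(res$retained$snp, c("rs4", "rs6"))
  expect_equal(res$excluded$reason[res$excluded$snp == "rs1"], "maf")
  expect_equal(res$excluded$reason[res$excluded$snp == "rs2"], "missing")
  expect_equal(res$excluded$reason[res$excluded$snp == "rs5"], "maf+missing")
  expect_equal(nrow(res$retained) + nrow(res$excluded), nrow(snps))

  # idempotent, and identity when everything passes
  again <- filter_snps(res$retained, 0.01, 0.05)
  expect_identical(again$retained$snp, res$retained$snp)
  expect_equal(nrow(again$excluded), 0)

  # marker at exactly the MAF threshold is retained (filter is maf < min)
  at <- filter_snps(data.frame(chr = "1", snp = "rsX", bp = 1, maf = 0.01,
                               f_miss = 0), 0.01, 0.05)
  expect_equal(nrow(at$retained), 1)
})

test_that("tables without QC columns pass with a warning", {
  snps <- data.frame(chr = "1", snp = c("a", "b"), bp = c(1, 2),
                     p = c(0.1, 0.2))
  expect_warning(expect_warning(res <- filter_snps(snps), "maf"), "f_miss")
  expect_equal(nrow(res$retained), 2)
})

test_that("chi-square type-I error rate is nominal under the null", {
  set.seed(14)
  n <- 1e5
  counts <- simulate_genotype_counts(rep(0.3, n), rep(0.3, n), 1000, 1000)
  counts <- cbind(data.frame(chr = "1", snp = sprintf("rs%d", 1:n),
                             bp = 1:n), counts)
  assoc <- assoc_from_counts(counts)
  rate <- mean(assoc$p < 0.05, na.rm = TRUE)
  band <- binom_band99(0.05, n)
  expect_gt(rate, band[1])
  expect_lt(rate, band[2])
})

test_that("pool t-test type-I error rate is nominal under the null", {
  set.seed(15)
  n <- 2e4
  make_pools <- function(k) list(
    snps = data.frame(chr = "1", snp = sprintf("rs%d", 1:n), bp = 1:n),
    case = matrix(rnorm(k * n, 0.5, 0.02), n, k),
    control = matrix(rnorm(k * n, 0.5, 0.02), n, k))
  band <- binom_band99(0.05, n)

  # pooled-variance Student t is exact under equal-variance Gaussian noise
  p4 <- make_pools(4)
  student_rate <- mean(assoc_from_pools(p4, var_equal = TRUE)$p < 0.05)
  expect_gt(student_rate, band[1])
  expect_lt(student_rate, band[2])

  # Welch is known to be conservative at 4 pools per group (never
  # anticonservative) and approaches the nominal level as pools increase
  welch4 <- mean(assoc_from_pools(p4)$p < 0.05)
  expect_lt(welch4, band[2])
  expect_gt(welch4, 0.03)
  welch12 <- mean(assoc_from_pools(make_pools(12))$p < 0.05)
  expect_gt(welch12, band[1])
  expect_lt(welch12, band[2])
})

test_that("vectorized pool association matches the scalar test", {
  set.seed(16)
  pools <- list(
    snps = data.frame(chr = "1", snp = c("a", "b"), bp = c(1, 2)),
    case = matrix(runif(8, 0.4, 0.6), 2),
    control = matrix(runif(10, 0.4, 0.6), 2, 5))
  assoc <- assoc_from_pools(pools)
  for (i in 1:2) {
    expect_equal(assoc$p[i],
                 pool_ttest(pools$case[i, ], pools$control[i, ])$p_value,
                 tolerance = 1e-12)
  }
})
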