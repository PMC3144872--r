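small_cfg <- function(..., n_risk_regions = 5) {
  sim_config(n_chromosomes = 3, chrom_length = 2e6, n_snps_a = 6000,
             n_snps_b = 6000, n_risk_regions = n_risk_regions, ...)
}

test_that("shared markers are placed identically on both platforms", {
  cfg <- small_cfg(seed = 61)
  maps <- simulate_snp_maps(cfg)
  n_sh <- round(cfg$shared_fraction * min(cfg$n_snps_a, cfg$n_snps_b))
  expect_equal(nrow(maps$shared), n_sh)
  a_sh <- maps$map_a[grepl("^rsS", maps$map_a$snp), ]
  b_sh <- maps$map_b[grepl("^rsS", maps$map_b$snp), ]
  expect_equal(nrow(a_sh), n_sh)
  a_sh <- a_sh[order(a_sh$snp), ]
  b_sh <- b_sh[order(b_sh$snp), ]
  expect_equal(a_sh$bp, b_sh$bp)
  expect_equal(a_sh$chr, b_sh$chr)
  # platform-specific markers have disjoint ids
  expect_length(intersect(setdiff(maps$map_a$snp, a_sh$snp),
                          setdiff(maps$map_b$snp, b_sh$snp)), 0)
  # positions unique within each chromosome of each map
  for (m in list(maps$map_a, maps$map_b)) {
    expect_false(any(unlist(lapply(split(m$bp, m$chr), duplicated))))
  }
})

test_that("shared fraction 0 gives fully disjoint marker sets", {
  maps <- simulate_snp_maps(small_cfg(shared_fraction = 0, seed = 62))
  expect_length(intersect(maps$map_a$snp, maps$map_b$snp), 0)
  expect_equal(nrow(maps$shared), 0)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 63)
  d1 <- simulate_gwas_pair(cfg)
  d2 <- simulate_gwas_pair(cfg)
  expect_identical(d1$snps_a, d2$snps_a)
  expect_identical(d1$snps_b, d2$snps_b)
  expect_identical(d1$truth$regions, d2$truth$regions)
  g1 <- simulate_gene_models(small_cfg(seed = 64), d1$truth, n_genes = 40)
  g2 <- simulate_gene_models(small_cfg(seed = 64), d1$truth, n_genes = 40)
  expect_identical(g1$tx_start, g2$tx_start)
})

test_that("density too high for the requested marker count errors", {
  expect_error(simulate_snp_maps(sim_config(n_chromosomes = 1,
                                            chrom_length = 100,
                                            n_snps_a = 200, n_snps_b = 50,
                                            seed = 1)),
               "density too high")
})

test_that("null p-values are uniform and risk p-values Beta-enriched", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 5e6, n_snps_a = 5e4,
                    n_snps_b = 1000, n_risk_regions = 0, seed = 65)
  d <- simulate_gwas_pair(cfg)
  ks <- ks.test(d$snps_a$p, "punif")
  expect_gt(ks$p.value, 0.001)

  # planted members: per-SNP power P(p < 0.05) = 0.05^a for Beta(a, 1)
  cfg2 <- small_cfg(seed = 66, n_risk_regions = 8)
  d2 <- simulate_gwas_pair(cfg2)
  risk <- d2$snps_a$snp %in% unlist(d2$truth$members_a)
  expect_gt(sum(risk), 8 * cfg2$snps_per_risk_region - 1)
  rate <- mean(d2$snps_a$p[risk] < 0.05)
  expected <- 0.05^cfg2$risk_p_beta[1]
  band <- binom_band99(expected, sum(risk))
  expect_gt(rate, band[1])
  expect_lt(rate, band[2])

  # Beta(1,1) risk SNPs are indistinguishable from the null
  cfg3 <- small_cfg(seed = 67, risk_p_beta = c(1, 1))
  d3 <- simulate_gwas_pair(cfg3)
  risk3 <- d3$snps_a$snp %in% unlist(d3$truth$members_a)
  expect_gt(ks.test(d3$snps_a$p[risk3], "punif")$p.value, 0.001)
})

test_that("planted regions respect density, disjointness and separation", {
  cfg <- small_cfg(seed = 68, n_risk_regions = 10)
  params <- scan_params()
  maps <- simulate_snp_maps(cfg)
  truth <- plant_risk_regions(maps, cfg, params)
  expect_equal(nrow(truth$regions), 10)
  expect_true(all(lengths(truth$members_a) >= cfg$snps_per_risk_region))
  expect_true(all(lengths(truth$members_b) >= cfg$snps_per_risk_region))
  r <- truth$regions
  for (ch in unique(r$chr)) {
    rc <- r[r$chr == ch, ]
    if (nrow(rc) > 1) {
      gaps <- rc$start[-1] - rc$end[-nrow(rc)] - 1
      expect_true(all(gaps > params$max_gap))
    }
  }
  # window width is twice the gap threshold: dense member counts, and any
  # two significant members are at most 2 * max_gap apart
  expect_true(all(r$end - r$start + 1 == 2 * params$max_gap))

  empty <- plant_risk_regions(maps, small_cfg(n_risk_regions = 0, seed = 1),
                              params)
  expect_equal(nrow(empty$regions), 0)

  sparse <- sim_config(n_chromosomes = 1, chrom_length = 1e7,
                       n_snps_a = 50, n_snps_b = 50, n_risk_regions = 5,
                       snps_per_risk_region = 6, seed = 69)
  sparse_maps <- simulate_snp_maps(sparse)
  expect_error(plant_risk_regions(sparse_maps, sparse, params,
                                  max_tries = 50), "cannot place regions")
})

test_that("pool noise has the configured spread and calibrated type I error", {
  cfg <- sim_config(seed = 70, n_pools_per_group = 4, pool_noise_sd = 0.02)
  exact <- simulate_pools(0.4, 0.3, sim_config(pool_noise_sd = 0))
  expect_equal(exact$case, rep(0.4, 4))
  expect_equal(exact$control, rep(0.3, 4))

  set.seed(71)
  ests <- replicate(4000, simulate_pools(0.5, 0.5, cfg)$case[1])
  expect_equal(sd(ests), 0.02, tolerance = 0.05)

  # the pooled-variance variant is exact under equal-variance Gaussian
  # noise; Welch at 4 pools per group is slightly conservative
  set.seed(72)
  ps <- replicate(4000, {
    pools <- simulate_pools(0.5, 0.5, cfg)
    c(pool_ttest(pools$case, pools$control, var_equal = TRUE)$p_value,
      pool_ttest(pools$case, pools$control)$p_value)
  })
  band <- binom_band99(0.05, 4000)
  expect_gt(mean(ps[1, ] < 0.05), band[1])
  expect_lt(mean(ps[1, ] < 0.05), band[2])
  expect_lte(mean(ps[2, ] < 0.05), mean(ps[1, ] < 0.05) + 0.005)
})

test_that("genotype counts follow HWE binomial sampling", {
  set.seed(73)
  n <- 5000
  counts <- simulate_genotype_counts(rep(0.2, n), rep(0.2, n), 500, 400)
  expect_true(all(counts$case_minor + counts$case_major == 1000))
  expect_true(all(counts$control_minor + counts$control_major == 800))
  expect_equal(mean(counts$case_minor), 1000 * 0.2, tolerance = 0.02)

  extreme <- simulate_genotype_counts(1, 0, 100, 100)
  expect_equal(extreme$case_minor, 200)
  expect_equal(extreme$control_minor, 0)
  res <- chi2_allelic(c(extreme$case_minor, extreme$case_major),
                      c(extreme$control_minor, extreme$control_major))
  expect_equal(res$statistic, 400) # fully separated table: chi2 = n
})

test_that("genes placed over planted regions are recovered by annotation", {
  cfg <- small_cfg(seed = 74)
  d <- simulate_gwas_pair(cfg)
  genes <- simulate_gene_models(cfg, d$truth, n_genes = 60)
  idx <- build_annotation_index(genes, flank = 10000)
  hit <- vapply(seq_len(nrow(d$truth$regions)), function(i) {
    length(annotate_region(d$truth$regions[i, ], idx)) > 0
  }, logical(1))
  expect_true(all(hit))
  # gene bodies never overlap each other
  for (ch in unique(genes$chr)) {
    g <- genes[genes$chr == ch, ]
    g <- g[order(g$tx_start), ]
    if (nrow(g) > 1) {
      expect_true(all(g$tx_start[-1] > g$tx_end[-nrow(g)]))
    }
  }
})

test_that("planted signal is recovered while false overlap stays at null level", {
  recovered <- numeric(3)
  for (i in 1:3) {
    cfg <- sim_config(seed = 80 + i)
    d <- simulate_gwas_pair(cfg)
    params <- scan_params()
    ra <- find_clusters(select_nominal(d$snps_a, params$alpha), params)
    rb <- find_clusters(select_nominal(d$snps_b, params$alpha), params)
    ov <- overlap_regions(ra, rb)
    hit_truth <- vapply(seq_len(nrow(d$truth$regions)), function(k) {
      tr <- d$truth$regions[k, ]
      any(ov$chr == tr$chr & ov$start <= tr$end & ov$end >= tr$start)
    }, logical(1))
    recovered[i] <- mean(hit_truth)
    in_truth <- vapply(seq_len(nrow(ov)), function(k) {
      any(d$truth$regions$chr == ov$chr[k] &
            d$truth$regions$start <= ov$end[k] &
            d$truth$regions$end >= ov$start[k])
    }, logical(1))
    mc <- mc_overlap_null(snp_map(d$snps_a), snp_map(d$snps_b), params,
                          n_trials = 200, seed = 90 + i)
    null_bound <- mean(mc$trial_stats) + 3 * sd(mc$trial_stats)
    expect_lt(sum(!in_truth), null_bound)
  }
  expect_true(all(recovered >= 0.8))
})
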