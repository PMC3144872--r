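# Per-SNP association tests and QC filters.
#
# Two designs are supported: individual genotyping, where case and control
# minor/major allele counts feed a 1-df Pearson chi-square on the 2x2 allele
# table, and pooled-DNA genotyping, where per-pool minor-allele frequency
# estimates from multiple case and control pools feed a two-sample t-test.

# Vectorized 2x2 allelic chi-square core: a/b = case minor/major counts,
# c/d = control minor/major. Returns the statistic; NA where a margin is zero.
chi2_stat_vec <- function(a, b, c, d) {
  # double arithmetic: the product of the four margins overflows integers
  a <- as.numeric(a)
  b <- as.numeric(b)
  c <- as.numeric(c)
  d <- as.numeric(d)
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  c2 <- b + d
  n <- r1 + r2
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  stat[r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0] <- NA_real_
  stat
}

# Vectorized two-sample t core on row matrices (one row per SNP).
# Returns list(statistic, df, p). Welch by default; pooled variance optional.
ttest_core <- function(xm, xv, nx, ym, yv, ny, var_equal = FALSE) {
  if (var_equal) {
    sp2 <- ((nx - 1) * xv + (ny - 1) * yv) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- rep.int(nx + ny - 2, length(xm))
  } else {
    se <- sqrt(xv / nx + yv / ny)
    df <- (xv / nx + yv / ny)^2 /
      ((xv / nx)^2 / (nx - 1) + (yv / ny)^2 / (ny - 1))
  }
  stat <- (xm - ym) / se
  zero <- !is.na(se) & se == 0
  stat[zero & xm == ym] <- 0
  p <- 2 * stats::pt(-abs(stat), df)
  p[zero & xm == ym] <- 1
  list(statistic = stat, df = df, p = p)
}

assoc_result <- function(statistic, df, p_value) {
  structure(list(statistic = statistic, df = df, p_value = p_value),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("statistic = %.6g, df = %.4g, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Allelic chi-square test on a 2x2 case/control allele-count table
#'
#' One-degree-of-freedom Pearson chi-square without continuity correction,
#' the standard allelic GWAS test for individually genotyped samples.
#' Computed by the closed form \eqn{n(ad - bc)^2 / (r_1 r_2 c_1 c_2)} with
#' the p-value from the upper tail of the chi-square distribution.
#'
#' @param case_alleles length-2 numeric, (minor, major) allele counts in cases.
#' @param control_alleles length-2 numeric, (minor, major) counts in controls.
#' @return An `assoc_result`: list with `statistic`, `df` (= 1), `p_value`.
#' @export
#' @examples
#' chi2_allelic(c(60, 40), c(40, 60)) # statistic 8, p ~ 4.7e-3
chi2_allelic <- function(case_alleles, control_alleles) {
  if (length(case_alleles) != 2 || length(control_alleles) != 2) {
    stop("allele counts must be length-2 (minor, major)", call. = FALSE)
  }
  cnt <- c(case_alleles, control_alleles)
  if (any(!is.finite(cnt)) || any(cnt < 0)) {
    stop("allele counts must be non-negative numbers", call. = FALSE)
  }
  stat <- chi2_stat_vec(case_alleles[1], case_alleles[2],
                        control_alleles[1], control_alleles[2])
  if (is.na(stat)) {
    stop("degenerate table: zero marginal (empty group or monomorphic SNP)",
         call. = FALSE)
  }
  assoc_result(stat, 1, stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Multi-pool t-test on per-pool allele-frequency estimates
#'
#' Two-sided two-sample t-test comparing minor-allele frequency estimates
#' from multiple case DNA pools against multiple control pools. The Welch
#' (unequal-variance) variant with Welch-Satterthwaite degrees of freedom is
#' the default; set `var_equal = TRUE` for the pooled-variance Student test.
#'
#' @param case_pools numeric vector of per-pool frequency estimates in cases
#'   (at least 2 pools).
#' @param control_pools numeric vector of per-pool estimates in controls.
#' @param var_equal use the pooled-variance Student t instead of Welch.
#' @return An `assoc_result`: list with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' pool_ttest(c(0.60, 0.62, 0.58, 0.61), c(0.50, 0.49, 0.52, 0.51))
pool_ttest <- function(case_pools, control_pools, var_equal = FALSE) {
  x <- as.numeric(case_pools)
  y <- as.numeric(control_pools)
  if (length(x) < 2 || length(y) < 2) {
    stop("insufficient pools: need at least 2 pools per group", call. = FALSE)
  }
  if (any(!is.finite(c(x, y))) || any(c(x, y) < 0) || any(c(x, y) > 1)) {
    stop("pool frequency estimates must lie in [0, 1]", call. = FALSE)
  }
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    stop("degenerate variance: both groups constant", call. = FALSE)
  }
  res <- ttest_core(mean(x), vx, length(x), mean(y), vy, length(y),
                    var_equal = var_equal)
  assoc_result(res$statistic, res$df, res$p)
}

#' Apply marker QC filters (minor-allele frequency and missing call rate)
#'
#' Retains SNPs with `maf >= maf_min` and `missing rate <= missing_max`.
#' Records lacking a QC field pass that filter (with a warning when the
#' whole column is absent), so pre-filtered public association tables can
#' flow through unchanged. Input order is preserved.
#'
#' @param snps data frame with columns `chr`, `snp`, `bp` and optionally
#'   `maf`, `f_miss`.
#' @param maf_min minimum minor-allele frequency (typically 0.01-0.02).
#' @param missing_max maximum missing call rate (default 0.05).
#' @return list with `retained` (filtered data frame) and `excluded`
#'   (data frame with `snp` and `reason`, one row per dropped marker).
#' @export
filter_snps <- function(snps, maf_min = 0.01, missing_max = 0.05) {
  check_snp_table(snps)
  if (maf_min < 0 || maf_min > 0.5) {
    stop("maf_min must lie in [0, 0.5]", call. = FALSE)
  }
  if (missing_max < 0 || missing_max > 1) {
    stop("missing_max must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(snps)
  if (n == 0) {
    return(list(retained = snps,
                excluded = data.frame(snp = character(), reason = character(),
                                      stringsAsFactors = FALSE)))
  }
  if ("maf" %in% names(snps)) {
    maf_fail <- !is.na(snps$maf) & snps$maf < maf_min
  } else {
    warning("no 'maf' column: MAF filter skipped", call. = FALSE)
    maf_fail <- rep.int(FALSE, n)
  }
  if ("f_miss" %in% names(snps)) {
    miss_fail <- !is.na(snps$f_miss) & snps$f_miss > missing_max
  } else {
    warning("no 'f_miss' column: missing-rate filter skipped", call. = FALSE)
    miss_fail <- rep.int(FALSE, n)
  }
  drop <- maf_fail | miss_fail
  reason <- character(sum(drop))
  reason[maf_fail[drop] & !miss_fail[drop]] <- "maf"
  reason[!maf_fail[drop] & miss_fail[drop]] <- "missing"
  reason[maf_fail[drop] & miss_fail[drop]] <- "maf+missing"
  list(retained = snps[!drop, , drop = FALSE],
       excluded = data.frame(snp = snps$snp[drop], reason = reason,
                             stringsAsFactors = FALSE))
}

#' Per-SNP chi-square association from a genotype-count table
#'
#' Vectorized allelic chi-square over a table of case/control minor/major
#' allele counts; monomorphic markers get `NA` p-values and are reported.
#'
#' @param counts data frame with columns `chr`, `snp`, `bp`, `case_minor`,
#'   `case_major`, `control_minor`, `control_major`.
#' @return SNP association table (`chr`, `snp`, `bp`, `p`, `maf`) where `maf`
#'   is the minor-allele frequency over all subjects combined.
#' @export
assoc_from_counts <- function(counts) {
  need <- c("chr", "snp", "bp", "case_minor", "case_major",
            "control_minor", "control_major")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    stop("counts table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  stat <- chi2_stat_vec(counts$case_minor, counts$case_major,
                        counts$control_minor, counts$control_major)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  tot <- counts$case_minor + counts$case_major +
    counts$control_minor + counts$control_major
  minor <- counts$case_minor + counts$control_minor
  data.frame(chr = norm_chrom(counts$chr), snp = counts$snp, bp = counts$bp,
             p = p, maf = pmin(minor / tot, 1 - minor / tot),
             stringsAsFactors = FALSE)
}

#' Per-SNP t-test association from pooled allele-frequency estimates
#'
#' Vectorized over SNPs: each row's case-pool estimates are compared against
#' its control-pool estimates with [pool_ttest()]'s math.
#'
#' @param pools list as returned by [read_pool_table()]: `snps` (data frame
#'   with `chr`, `snp`, `bp`), `case` and `control` (numeric matrices, one
#'   row per SNP, one column per pool).
#' @param var_equal use pooled-variance Student t instead of Welch.
#' @return SNP association table (`chr`, `snp`, `bp`, `p`).
#' @export
assoc_from_pools <- function(pools, var_equal = FALSE) {
  x <- pools$case
  y <- pools$control
  if (ncol(x) < 2 || ncol(y) < 2) {
    stop("insufficient pools: need at least 2 pools per group", call. = FALSE)
  }
  xm <- rowMeans(x)
  ym <- rowMeans(y)
  xv <- rowSums((x - xm)^2) / (ncol(x) - 1)
  yv <- rowSums((y - ym)^2) / (ncol(y) - 1)
  res <- ttest_core(xm, xv, ncol(x), ym, yv, ncol(y), var_equal = var_equal)
  data.frame(chr = norm_chrom(pools$snps$chr), snp = pools$snps$snp,
             bp = pools$snps$bp, p = res$p, stringsAsFactors = FALSE)
}
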