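# Synthetic dual-platform GWAS generator.
#
# Emulates the statistical structure the pipeline assumes: two genotyping
# platforms whose autosomal marker maps share a controllable fraction of
# positions (~1/4 by default, as for 1M-class arrays from different
# vendors), uniform null p-values, planted shared risk regions whose member
# SNPs draw small-p-enriched Beta(a, 1) p-values, per-pool allele-frequency
# noise with SD 0.02, and HWE binomial genotype counts for the chi-square
# path. Linkage disequilibrium is deliberately not modeled: risk signal is
# injected directly at the p-value (or allele-frequency) level, which keeps
# per-SNP power closed-form.

#' Configuration for the synthetic-data generator
#'
#' @param n_chromosomes number of (autosomal) chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param n_snps_a,n_snps_b marker counts for the two platforms.
#' @param shared_fraction fraction of the smaller platform's markers placed
#'   at identical positions (and ids) on both platforms.
#' @param n_risk_regions number of planted shared risk regions.
#' @param snps_per_risk_region minimum markers per platform inside each
#'   planted region (must be >= the scan's `min_cluster_size`).
#' @param risk_p_beta length-2 `(a, b)` shape parameters of the Beta
#'   p-value distribution at risk SNPs; `a < 1` enriches small p
#'   (per-risk-SNP power at alpha is `alpha^a` when `b = 1`).
#' @param pool_noise_sd per-pool allele-frequency noise SD (default 0.02).
#' @param n_pools_per_group DNA pools per phenotype group.
#' @param n_case,n_control subject counts for genotype-count simulation.
#' @param seed RNG seed applied by the generator functions.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 10, chrom_length = 1.2e7,
                       n_snps_a = 1e5, n_snps_b = 1e5,
                       shared_fraction = 0.25,
                       n_risk_regions = 20, snps_per_risk_region = 6,
                       risk_p_beta = c(0.1, 1),
                       pool_noise_sd = 0.02, n_pools_per_group = 4,
                       n_case = 1000, n_control = 1000, seed = NULL) {
  stopifnot(n_chromosomes >= 1, chrom_length >= 1,
            n_snps_a >= 1, n_snps_b >= 1,
            shared_fraction >= 0, shared_fraction <= 1,
            n_risk_regions >= 0, snps_per_risk_region >= 2,
            length(risk_p_beta) == 2, all(risk_p_beta > 0),
            pool_noise_sd >= 0, n_pools_per_group >= 2)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d chrom x %g bp; %g + %g SNPs (%.0f%% shared); %d risk regions\n",
    x$n_chromosomes, x$chrom_length, x$n_snps_a, x$n_snps_b,
    100 * x$shared_fraction, x$n_risk_regions))
  invisible(x)
}

chrom_sizes_from_config <- function(config) {
  setNames(rep.int(config$chrom_length, config$n_chromosomes),
           as.character(seq_len(config$n_chromosomes)))
}

# Draw k distinct positions on 1..L, avoiding `exclude`.
draw_positions <- function(L, k, exclude = numeric()) {
  if (k > L - length(exclude)) stop("density too high", call. = FALSE)
  pos <- unique(sample.int(L, min(L, k + length(exclude) + 1000L)))
  pos <- setdiff(pos, exclude)
  while (length(pos) < k) {
    pos <- setdiff(unique(c(pos, sample.int(L, k))), exclude)
  }
  sort(pos[seq_len(k)])
}

#' Simulate two platforms' SNP maps with a shared marker fraction
#'
#' Positions are uniform on each chromosome; a `shared_fraction` of the
#' smaller platform's markers is placed at identical positions with a
#' common id on both maps.
#'
#' @param config a [sim_config()].
#' @return list with `map_a`, `map_b` (data frames `chr`, `snp`, `bp`,
#'   sorted, with attribute `platform`), and `shared` (data frame of the
#'   common markers).
#' @export
simulate_snp_maps <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$chrom_length
  n_sh <- round(config$shared_fraction * min(config$n_snps_a, config$n_snps_b))
  alloc <- function(n) tabulate(sample.int(config$n_chromosomes, n,
                                           replace = TRUE),
                                nbins = config$n_chromosomes)
  sh_per <- alloc(n_sh)
  a_per <- alloc(config$n_snps_a - n_sh)
  b_per <- alloc(config$n_snps_b - n_sh)
  sh_pos <- lapply(seq_len(config$n_chromosomes),
                   function(ch) draw_positions(L, sh_per[ch]))
  a_pos <- lapply(seq_len(config$n_chromosomes), function(ch) {
    draw_positions(L, a_per[ch], exclude = sh_pos[[ch]])
  })
  b_pos <- lapply(seq_len(config$n_chromosomes), function(ch) {
    draw_positions(L, b_per[ch], exclude = sh_pos[[ch]])
  })
  build <- function(spec_pos, prefix) {
    chr <- c(rep.int(as.character(seq_len(config$n_chromosomes)), sh_per),
             rep.int(as.character(seq_len(config$n_chromosomes)),
                     lengths(spec_pos)))
    bp <- c(unlist(sh_pos), unlist(spec_pos))
    snp <- c(sprintf("rsS%06d", seq_len(n_sh)),
             sprintf("rs%s%06d", prefix, seq_along(unlist(spec_pos))))
    df <- data.frame(chr = chr, snp = snp, bp = bp, stringsAsFactors = FALSE)
    df <- df[chrom_order(df$chr, df$bp), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  map_a <- build(a_pos, "A")
  map_b <- build(b_pos, "B")
  attr(map_a, "platform") <- "a"
  attr(map_b, "platform") <- "b"
  shared <- data.frame(
    snp = sprintf("rsS%06d", seq_len(n_sh)),
    chr = rep.int(as.character(seq_len(config$n_chromosomes)), sh_per),
    bp = unlist(sh_pos), stringsAsFactors = FALSE)
  list(map_a = map_a, map_b = map_b, shared = shared)
}

#' Plant shared risk regions on a pair of maps
#'
#' Chooses disjoint windows of width twice `max_gap` (narrow enough that
#' member SNPs virtually always chain at realistic densities, wide enough
#' to hold a robust member count), each containing at least
#' `snps_per_risk_region` markers on BOTH platforms, with successive regions
#' separated by more than `max_gap`. All markers inside a window become
#' risk-region members for their platform.
#'
#' @param maps output of [simulate_snp_maps()].
#' @param config a [sim_config()].
#' @param params [scan_params()] supplying `max_gap`.
#' @param max_tries placement attempts per region before giving up.
#' @return object of class `synthetic_truth`: `regions` (data frame `chr`,
#'   `start`, `end`) and list-columns-by-region `members_a`, `members_b`
#'   (SNP ids per platform).
#' @export
plant_risk_regions <- function(maps, config, params = scan_params(),
                               max_tries = 500) {
  stopifnot(inherits(config, "sim_config"))
  width <- 2 * params$max_gap
  k <- config$snps_per_risk_region
  n <- config$n_risk_regions
  regions <- data.frame(chr = character(), start = numeric(),
                        end = numeric(), stringsAsFactors = FALSE)
  members_a <- list()
  members_b <- list()
  if (n == 0) {
    return(structure(list(regions = regions, members_a = members_a,
                          members_b = members_b),
                     class = "synthetic_truth"))
  }
  by_chr_a <- split(maps$map_a[c("bp", "snp")], maps$map_a$chr)
  by_chr_b <- split(maps$map_b[c("bp", "snp")], maps$map_b$chr)
  in_window <- function(tab, s, e) {
    lo <- findInterval(s - 0.5, tab$bp) + 1L
    hi <- findInterval(e + 0.5, tab$bp)
    if (hi < lo) character() else tab$snp[lo:hi]
  }
  for (r in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- as.character(sample.int(config$n_chromosomes, 1))
      s <- sample.int(config$chrom_length - width + 1, 1)
      e <- s + width - 1
      prev <- regions$chr == ch
      if (any(prev & regions$start - params$max_gap - 1 <= e &
              regions$end + params$max_gap + 1 >= s)) next
      ma <- in_window(by_chr_a[[ch]], s, e)
      mb <- in_window(by_chr_b[[ch]], s, e)
      if (length(ma) < k || length(mb) < k) next
      regions <- rbind(regions, data.frame(chr = ch, start = s, end = e,
                                           stringsAsFactors = FALSE))
      members_a[[r]] <- ma
      members_b[[r]] <- mb
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("cannot place regions: marker density too low for the requested ",
           "risk-region layout", call. = FALSE)
    }
  }
  o <- chrom_order(regions$chr, regions$start)
  structure(list(regions = regions[o, , drop = FALSE],
                 members_a = members_a[o], members_b = members_b[o]),
            class = "synthetic_truth")
}

#' Simulate per-SNP p-values for one platform
#'
#' Non-risk markers draw independent Uniform(0, 1) p-values; members of
#' planted risk regions draw Beta(a, b) with `a < 1` (small-p enriched).
#'
#' @param map one platform's map from [simulate_snp_maps()].
#' @param truth a [plant_risk_regions()] object, or NULL for a pure null.
#' @param config a [sim_config()] (supplies `risk_p_beta`).
#' @param platform "a" or "b"; taken from the map's attribute when absent.
#' @return the map with a `p` column added.
#' @export
simulate_pvalues <- function(map, truth = NULL, config = sim_config(),
                             platform = attr(map, "platform")) {
  p <- runif(nrow(map))
  if (!is.null(truth) && length(truth$members_a)) {
    members <- if (identical(platform, "b")) truth$members_b
               else truth$members_a
    risk <- map$snp %in% unlist(members)
    p[risk] <- rbeta(sum(risk), config$risk_p_beta[1], config$risk_p_beta[2])
  }
  map$p <- p
  map
}

#' Simulate per-pool allele-frequency estimates for one SNP
#'
#' Each pool's estimate is the group's true frequency plus Gaussian noise
#' (SD `pool_noise_sd`), truncated to [0, 1].
#'
#' @param true_freq_case,true_freq_control true minor-allele frequencies.
#' @param config a [sim_config()].
#' @return list with numeric vectors `case` and `control`, one estimate per
#'   pool.
#' @export
simulate_pools <- function(true_freq_case, true_freq_control,
                           config = sim_config()) {
  stopifnot(true_freq_case >= 0, true_freq_case <= 1,
            true_freq_control >= 0, true_freq_control <= 1)
  k <- config$n_pools_per_group
  clamp <- function(x) pmin(pmax(x, 0), 1)
  list(case = clamp(rnorm(k, true_freq_case, config$pool_noise_sd)),
       control = clamp(rnorm(k, true_freq_control, config$pool_noise_sd)))
}

#' Simulate 2x2 allele-count tables under Hardy-Weinberg equilibrium
#'
#' Minor-allele counts are binomial draws over `2n` alleles per group.
#' Vectorized over SNPs.
#'
#' @param freq_case,freq_control true minor-allele frequencies (vectors).
#' @param n_case,n_control subject counts.
#' @return data frame with columns `case_minor`, `case_major`,
#'   `control_minor`, `control_major`, one row per SNP.
#' @export
simulate_genotype_counts <- function(freq_case, freq_control,
                                     n_case, n_control) {
  stopifnot(all(freq_case >= 0 & freq_case <= 1),
            all(freq_control >= 0 & freq_control <= 1),
            n_case >= 1, n_control >= 1)
  m <- max(length(freq_case), length(freq_control))
  a <- rbinom(m, 2 * n_case, freq_case)
  c_ <- rbinom(m, 2 * n_control, freq_control)
  data.frame(case_minor = a, case_major = 2 * n_case - a,
             control_minor = c_, control_major = 2 * n_control - c_)
}

#' Simulate gene models
#'
#' Non-overlapping multi-exon genes with plausible spans (5-100 kb),
#' terminal exons flush with the transcript bounds. When `truth` is given,
#' one gene is placed over each planted region so annotation recovery can
#' be scored; the remaining genes are placed at random (yielding natural
#' intron-only and no-gene test cases).
#'
#' @param config a [sim_config()].
#' @param truth optional [plant_risk_regions()] object.
#' @param n_genes total number of genes to attempt (default 200).
#' @return a [gene_models()] table.
#' @export
simulate_gene_models <- function(config, truth = NULL, n_genes = 200) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 7919L)
  L <- config$chrom_length
  placed <- data.frame(chr = character(), start = numeric(), end = numeric(),
                       stringsAsFactors = FALSE)
  rows <- list()
  add_gene <- function(ch, s, e, sym) {
    n_ex <- sample.int(8, 1)
    span <- e - s
    if (span < 2 * n_ex + 2) n_ex <- 1
    if (n_ex > 1) {
      b <- sort(sample((s + 1):(e - 1), 2 * (n_ex - 1)))
      ex_s <- c(s, b[seq(2, length(b), by = 2)] + 1)
      ex_e <- c(b[seq(1, length(b), by = 2)], e)
    } else {
      ex_s <- s
      ex_e <- e
    }
    df <- data.frame(symbol = sym, chr = ch,
                     strand = sample(c("+", "-"), 1),
                     tx_start = s, tx_end = e, stringsAsFactors = FALSE)
    df$exon_starts <- list(ex_s)
    df$exon_ends <- list(ex_e)
    df
  }
  free <- function(ch, s, e) {
    !any(placed$chr == ch & placed$start <= e & placed$end >= s)
  }
  gi <- 0
  if (!is.null(truth) && nrow(truth$regions)) {
    for (r in seq_len(nrow(truth$regions))) {
      gi <- gi + 1
      s <- max(1, truth$regions$start[r] - sample.int(20000, 1))
      e <- min(L, truth$regions$end[r] + sample.int(20000, 1))
      ch <- truth$regions$chr[r]
      if (!free(ch, s, e)) next
      rows[[length(rows) + 1]] <- add_gene(ch, s, e, sprintf("GENE%04d", gi))
      placed <- rbind(placed, data.frame(chr = ch, start = s, end = e,
                                         stringsAsFactors = FALSE))
    }
  }
  while (gi < n_genes) {
    gi <- gi + 1
    ch <- as.character(sample.int(config$n_chromosomes, 1))
    len <- sample(5000:100000, 1)
    if (len >= L) len <- max(1000, L %/% 10)
    s <- sample.int(L - len, 1)
    e <- s + len
    if (!free(ch, s, e)) next
    rows[[length(rows) + 1]] <- add_gene(ch, s, e, sprintf("GENE%04d", gi))
    placed <- rbind(placed, data.frame(chr = ch, start = s, end = e,
                                       stringsAsFactors = FALSE))
  }
  gene_models(do.call(rbind, rows))
}

#' Simulate a full dual-platform GWAS dataset pair
#'
#' Convenience wrapper: maps, planted truth (unless `n_risk_regions` is 0),
#' and p-values for both platforms.
#'
#' @param config a [sim_config()].
#' @param params [scan_params()] used for risk-region placement.
#' @return list with `snps_a`, `snps_b` (association tables with `p`),
#'   `truth` (a `synthetic_truth`), `shared`, and `chrom_sizes`.
#' @export
simulate_gwas_pair <- function(config = sim_config(),
                               params = scan_params()) {
  maps <- simulate_snp_maps(config)
  truth <- plant_risk_regions(maps, config, params)
  list(snps_a = simulate_pvalues(maps$map_a, truth, config, platform = "a"),
       snps_b = simulate_pvalues(maps$map_b, truth, config, platform = "b"),
       truth = truth, shared = maps$shared,
       chrom_sizes = chrom_sizes_from_config(config))
}
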