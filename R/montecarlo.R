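# Monte Carlo null distributions by "pseudo-positive" marker resampling.
#
# Both nulls keep every marker where the platform put it and only move the
# significance labels: each trial draws, uniformly without replacement from
# the full post-QC marker list, as many pseudo-positive SNPs as achieved
# nominal significance in the real data, then recomputes the statistic of
# interest (cluster count within a sample; merged overlap-region count
# between samples). Ties with the observed statistic count as exceedances.

#' Build a SNP map for Monte Carlo resampling
#'
#' A `snp_map` is one sample's full list of assayed (post-QC) markers with
#' their chromosomal positions, sorted by (chromosome, position), plus the
#' count of markers that achieved nominal significance in the real data.
#'
#' @param snps SNP table with columns `chr`, `snp`, `bp`; a `p` column, when
#'   present, determines `n_positive`.
#' @param alpha nominal threshold used for `n_positive` (strict inequality).
#' @param autosomes_only restrict to autosomes (default TRUE).
#' @return object of class `snp_map` with elements `chr`, `bp`, `snp`,
#'   `p` (or NULL), `n_total`, `n_positive` (NA when no p-values).
#' @export
snp_map <- function(snps, alpha = 0.05, autosomes_only = TRUE) {
  check_snp_table(snps)
  snps$chr <- norm_chrom(snps$chr)
  if (autosomes_only) snps <- snps[is_autosome(snps$chr), , drop = FALSE]
  snps <- snps[chrom_order(snps$chr, snps$bp), , drop = FALSE]
  has_p <- "p" %in% names(snps)
  structure(list(
    chr = as.character(snps$chr),
    bp = as.numeric(snps$bp),
    snp = as.character(snps$snp),
    p = if (has_p) snps$p else NULL,
    alpha = alpha,
    n_total = nrow(snps),
    n_positive = if (has_p) sum(!is.na(snps$p) & snps$p < alpha)
                 else NA_integer_),
    class = "snp_map")
}

#' @export
print.snp_map <- function(x, ...) {
  cat(sprintf("snp_map: %d markers on %d chromosome(s); %s nominally positive\n",
              x$n_total, length(unique(x$chr)),
              ifelse(is.na(x$n_positive), "?", x$n_positive)))
  invisible(x)
}

#' Draw pseudo-positive SNPs from a map
#'
#' Uniform sample without replacement of marker indices from the full
#' assayed list; uses the current RNG state (seed upstream for
#' reproducibility).
#'
#' @param map a [snp_map()].
#' @param n_positive number of pseudo-positives to draw.
#' @return sorted integer vector of marker indices into the map.
#' @export
draw_pseudopositives <- function(map, n_positive = map$n_positive) {
  if (is.na(n_positive)) stop("n_positive is unknown for this map",
                              call. = FALSE)
  if (n_positive > map$n_total) {
    stop("sample larger than population: n_positive > n_total", call. = FALSE)
  }
  if (n_positive == 0) return(integer())
  sort.int(sample.int(map$n_total, n_positive))
}

#' Add-one empirical p-value
#'
#' `(n_exceed + 1) / (n_trials + 1)`: never zero, so 0 exceedances in 10,000
#' trials reports ~1e-4 (conventionally "p < 0.0001") rather than 0.
#'
#' @param n_exceed number of trials whose statistic equaled or exceeded the
#'   observed statistic.
#' @param n_trials number of Monte Carlo trials (>= 1).
#' @return empirical p in (0, 1].
#' @export
#' @examples
#' empirical_p(0, 10000)
#' empirical_p(4, 99) # 0.05
empirical_p <- function(n_exceed, n_trials) {
  if (n_trials < 1) stop("no trials", call. = FALSE)
  if (n_exceed < 0 || n_exceed > n_trials) {
    stop("n_exceed must lie in [0, n_trials]", call. = FALSE)
  }
  (n_exceed + 1) / (n_trials + 1)
}

mc_result <- function(null_id, observed_stat, trial_stats, n_trials, seed,
                      params, extra = list()) {
  n_exceed <- sum(trial_stats >= observed_stat)
  structure(c(list(null_id = null_id,
                   observed_stat = observed_stat,
                   trial_stats = trial_stats,
                   n_exceed = n_exceed,
                   empirical_p = empirical_p(n_exceed, n_trials),
                   n_trials = n_trials,
                   seed = seed,
                   params = params),
              extra),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo %s null: observed %g, %d/%d trials >= observed\n",
              x$null_id, x$observed_stat, x$n_exceed, x$n_trials))
  cat(sprintf("empirical p = %.4g%s\n", x$empirical_p,
              if (x$n_exceed == 0)
                sprintf(" (p < %.4g)", 1 / x$n_trials) else ""))
  invisible(x)
}

# Per-trial sub-seeds derived from one master seed, so each trial is
# reproducible independently of execution order.
trial_seeds <- function(seed, n_trials) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_trials)
}

map_keys <- function(map, levels, offset) {
  encode_keys(map$chr, map$bp, levels, offset)
}

# Cluster regions of a drawn index set, in key space: matrix of run
# start/end keys for runs of size >= min_size with gaps <= max_gap.
runs_from_keys <- function(key, max_gap, min_size) {
  rb <- run_bounds(key, max_gap, min_size)
  cbind(start = key[rb$s], end = key[rb$e])
}

# Count merged connected components of pairwise intersections between two
# sorted, disjoint interval sets (closed intervals; sharing one base joins).
count_merged_overlaps <- function(ra, rb) {
  if (nrow(ra) == 0 || nrow(rb) == 0) return(0L)
  lo <- findInterval(rb[, 1] - 0.5, ra[, 2]) + 1L
  hi <- findInterval(rb[, 2] + 0.5, ra[, 1])
  nb <- pmax(hi - lo + 1L, 0L)
  total <- sum(nb)
  if (total == 0) return(0L)
  i <- sequence(nb, from = lo)
  j <- rep.int(seq_len(nrow(rb)), nb)
  s <- pmax(ra[i, 1], rb[j, 1])
  e <- pmin(ra[i, 2], rb[j, 2])
  o <- order(s)
  s <- s[o]
  e <- e[o]
  if (length(s) == 1L) return(1L)
  cm <- cummax(e)
  sum(c(TRUE, s[-1] > cm[-length(cm)]))
}

#' Monte Carlo null for within-sample clustering
#'
#' Tests the null hypothesis that the sample's nominally positive SNPs are
#' randomly arrayed along the chromosomes: each trial relabels a random set
#' of markers (same count as observed) as pseudo-positive and re-runs the
#' cluster scan. The trial statistic is the number of clusters; the number
#' of clustered SNPs is recorded alongside as a secondary statistic.
#'
#' @param map a [snp_map()] built from the sample's full post-QC marker list
#'   with p-values (used for the observed statistic unless supplied).
#' @param params [scan_params()] matching the real-data scan.
#' @param observed_stat observed cluster count; computed from the map's own
#'   significant set when NULL.
#' @param n_trials number of trials (default 10000).
#' @param seed master RNG seed (recorded in the result).
#' @param n_positive number of pseudo-positives per trial (defaults to the
#'   map's observed count).
#' @return object of class `mc_result`; see [empirical_p()] for the
#'   estimator. Includes `trial_snps` (clustered-SNP counts per trial) and
#'   `observed_snps`.
#' @export
mc_clustering_null <- function(map, params = scan_params(),
                               observed_stat = NULL, n_trials = 10000,
                               seed = NULL, n_positive = map$n_positive) {
  stopifnot(inherits(map, "snp_map"))
  levels <- chrom_levels(map$chr)
  offset <- max(map$bp) + params$max_gap + 2
  key <- map_keys(map, levels, offset)
  if (is.null(observed_stat)) {
    if (is.null(map$p)) {
      stop("observed_stat is required when the map has no p-values",
           call. = FALSE)
    }
    obs_idx <- which(!is.na(map$p) & map$p < params$alpha)
    rb <- run_bounds(key[obs_idx], params$max_gap, params$min_cluster_size)
    observed_stat <- length(rb$s)
    observed_snps <- sum(rb$e - rb$s + 1L)
  } else {
    observed_snps <- NA_integer_
  }
  seeds <- trial_seeds(seed, n_trials)
  stats <- integer(n_trials)
  snps <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    set.seed(seeds[t])
    idx <- draw_pseudopositives(map, n_positive)
    rb <- run_bounds(key[idx], params$max_gap, params$min_cluster_size)
    stats[t] <- length(rb$s)
    snps[t] <- sum(rb$e - rb$s + 1L)
  }
  mc_result("clustering", observed_stat, stats, n_trials, seed, params,
            extra = list(trial_snps = snps, observed_snps = observed_snps,
                         n_positive = n_positive))
}

#' Monte Carlo null for between-sample region overlap
#'
#' Tests the null hypothesis that the chromosomal regions identified by
#' clustered nominally positive SNPs in two independent samples coincide
#' only by chance: each trial independently relabels pseudo-positive markers
#' in both maps (each at its own observed count), clusters each, and counts
#' the merged overlap regions.
#'
#' @param map_a,map_b [snp_map()] objects for the two samples.
#' @param params [scan_params()] matching the real-data scans.
#' @param observed_stat observed merged overlap-region count; computed from
#'   the maps' own significant sets when NULL.
#' @param n_trials number of trials (default 10000).
#' @param seed master RNG seed.
#' @param n_positive_a,n_positive_b pseudo-positive counts per trial.
#' @return object of class `mc_result`.
#' @export
mc_overlap_null <- function(map_a, map_b, params = scan_params(),
                            observed_stat = NULL, n_trials = 10000,
                            seed = NULL,
                            n_positive_a = map_a$n_positive,
                            n_positive_b = map_b$n_positive) {
  stopifnot(inherits(map_a, "snp_map"), inherits(map_b, "snp_map"))
  levels <- chrom_levels(c(map_a$chr, map_b$chr))
  offset <- max(map_a$bp, map_b$bp) + params$max_gap + 2
  key_a <- map_keys(map_a, levels, offset)
  key_b <- map_keys(map_b, levels, offset)
  gap <- params$max_gap
  size <- params$min_cluster_size
  if (is.null(observed_stat)) {
    if (is.null(map_a$p) || is.null(map_b$p)) {
      stop("observed_stat is required when a map has no p-values",
           call. = FALSE)
    }
    ra <- runs_from_keys(key_a[!is.na(map_a$p) & map_a$p < params$alpha],
                         gap, size)
    rb <- runs_from_keys(key_b[!is.na(map_b$p) & map_b$p < params$alpha],
                         gap, size)
    observed_stat <- count_merged_overlaps(ra, rb)
  }
  seeds <- trial_seeds(seed, n_trials)
  stats <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    set.seed(seeds[t])
    ia <- draw_pseudopositives(map_a, n_positive_a)
    ib <- draw_pseudopositives(map_b, n_positive_b)
    stats[t] <- count_merged_overlaps(
      runs_from_keys(key_a[ia], gap, size),
      runs_from_keys(key_b[ib], gap, size))
  }
  mc_result("overlap", observed_stat, stats, n_trials, seed, params,
            extra = list(n_positive_a = n_positive_a,
                         n_positive_b = n_positive_b))
}
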