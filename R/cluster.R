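# Within-sample cluster scan: maximal runs of nominally significant SNPs in
# which every adjacent pair lies within a gap threshold.

#' Cluster-scan parameters
#'
#' Defaults match the criteria used for ~1M-SNP platforms: at least 4
#' clustered SNPs, each within 10 kb of the nearest other nominally
#' significant SNP, at nominal alpha 0.05. For sparser ~500K arrays a
#' common alternative is `min_cluster_size = 3`, `max_gap = 25000`.
#'
#' @param alpha nominal significance threshold (strict: p < alpha).
#' @param min_cluster_size minimum number of SNPs in a cluster (>= 2).
#' @param max_gap maximum base-pair separation between adjacent clustered
#'   SNPs (inclusive: a gap of exactly `max_gap` joins).
#' @return list of class `scan_params`.
#' @export
#' @examples
#' scan_params()
#' scan_params(min_cluster_size = 3, max_gap = 25000)
scan_params <- function(alpha = 0.05, min_cluster_size = 4, max_gap = 10000) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (min_cluster_size < 2) stop("min_cluster_size must be >= 2", call. = FALSE)
  if (max_gap < 1) stop("max_gap must be >= 1", call. = FALSE)
  structure(list(alpha = alpha,
                 min_cluster_size = as.integer(min_cluster_size),
                 max_gap = as.numeric(max_gap)),
            class = "scan_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat(sprintf("scan_params: alpha %g, >= %d SNPs, gaps <= %g bp\n",
              x$alpha, x$min_cluster_size, x$max_gap))
  invisible(x)
}

#' Select nominally significant SNPs
#'
#' Retains markers with `p < alpha` (strict inequality; ties at alpha are
#' non-significant), normalizes chromosome labels, restricts to autosomes
#' by default, and returns the records sorted by (chromosome, position) as
#' required by [find_clusters()].
#'
#' @param snps SNP association table with columns `chr`, `snp`, `bp`, `p`.
#' @param alpha nominal threshold (default 0.05).
#' @param autosomes_only drop sex/mitochondrial chromosomes (default TRUE).
#' @return sorted data frame of significant records.
#' @export
select_nominal <- function(snps, alpha = 0.05, autosomes_only = TRUE) {
  check_snp_table(snps, require_p = TRUE)
  snps$chr <- norm_chrom(snps$chr)
  keep <- !is.na(snps$p) & snps$p < alpha
  if (autosomes_only) keep <- keep & is_autosome(snps$chr)
  out <- snps[keep, , drop = FALSE]
  out <- out[chrom_order(out$chr, out$bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_regions <- function() {
  out <- data.frame(chr = character(), start = numeric(), end = numeric(),
                    n_snps = integer(), min_p = numeric(),
                    min_p_snp = character(), stringsAsFactors = FALSE)
  out$snps <- list()
  out
}

# Run detection on an encoded, sorted key vector: returns start/end indices
# of maximal runs whose adjacent gaps are all <= max_gap and whose size is
# >= min_size. Shared by the public scan and the Monte Carlo trial loop.
run_bounds <- function(key, max_gap, min_size) {
  n <- length(key)
  if (n == 0) {
    return(list(s = integer(), e = integer()))
  }
  brk <- c(TRUE, diff(key) > max_gap)
  s <- which(brk)
  e <- c(s[-1] - 1L, n)
  keep <- (e - s + 1L) >= min_size
  list(s = s[keep], e = e[keep])
}

#' Find clusters of nominally significant SNPs
#'
#' Single-linkage chain over significant SNPs only: per chromosome, maximal
#' runs in which every adjacent pair of significant SNPs is separated by at
#' most `max_gap` base pairs. Non-significant markers in between neither
#' join nor break a chain. Runs with at least `min_cluster_size` members
#' become regions whose bounds are the outermost member SNP positions
#' (1-based, closed).
#'
#' @param nominal data frame of significant SNPs sorted by (chromosome,
#'   position), e.g. from [select_nominal()]; all `p` must be below
#'   `params$alpha`.
#' @param params a [scan_params()] object.
#' @return data frame of regions: `chr`, `start`, `end`, `n_snps`, `min_p`,
#'   `min_p_snp`, plus a list-column `snps` of member SNP ids; disjoint and
#'   sorted within each chromosome.
#' @export
find_clusters <- function(nominal, params = scan_params()) {
  check_snp_table(nominal, require_p = TRUE)
  n <- nrow(nominal)
  if (n == 0) return(empty_regions())
  chr <- as.character(nominal$chr)
  bp <- as.numeric(nominal$bp)
  if (!is_position_sorted(chr, bp)) {
    stop("input not sorted by (chromosome, position)", call. = FALSE)
  }
  if (any(nominal$p >= params$alpha)) {
    stop("find_clusters() expects only nominally significant SNPs ",
         "(all p < alpha)", call. = FALSE)
  }
  levels <- chrom_levels(chr)
  offset <- max(bp) + params$max_gap + 2
  key <- encode_keys(chr, bp, levels, offset)
  rb <- run_bounds(key, params$max_gap, params$min_cluster_size)
  if (length(rb$s) == 0) return(empty_regions())
  k <- length(rb$s)
  min_p <- numeric(k)
  min_p_snp <- character(k)
  members <- vector("list", k)
  for (i in seq_len(k)) {
    idx <- rb$s[i]:rb$e[i]
    j <- idx[which.min(nominal$p[idx])]
    min_p[i] <- nominal$p[j]
    min_p_snp[i] <- nominal$snp[j]
    members[[i]] <- nominal$snp[idx]
  }
  out <- data.frame(chr = chr[rb$s], start = bp[rb$s], end = bp[rb$e],
                    n_snps = rb$e - rb$s + 1L, min_p = min_p,
                    min_p_snp = min_p_snp, stringsAsFactors = FALSE)
  out$snps <- members
  out
}

#' Fraction of the genome covered by regions
#'
#' Sum of closed-interval region lengths (`end - start + 1`) divided by the
#' total length of the chromosomes supplied (for an autosome-only analysis,
#' supply autosome sizes only).
#'
#' @param regions region data frame (`chr`, `start`, `end`).
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @return fraction in [0, 1].
#' @export
genome_fraction <- function(regions, chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(chrom_sizes <= 0)) {
    stop("chrom_sizes must be a named vector of positive lengths",
         call. = FALSE)
  }
  names(chrom_sizes) <- norm_chrom(names(chrom_sizes))
  if (nrow(regions) == 0) return(0)
  chr <- norm_chrom(regions$chr)
  if (!all(chr %in% names(chrom_sizes))) {
    stop("region chromosome(s) absent from chrom_sizes: ",
         paste(setdiff(chr, names(chrom_sizes)), collapse = ", "),
         call. = FALSE)
  }
  if (any(regions$start < 1) || any(regions$end > chrom_sizes[chr])) {
    stop("region out of bounds for its chromosome", call. = FALSE)
  }
  sum(regions$end - regions$start + 1) / sum(chrom_sizes)
}
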