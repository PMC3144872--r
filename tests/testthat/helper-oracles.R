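# Brute-force reference implementations and random-instance generators.
# These deliberately use different mechanisms from the package internals so
# they can serve as independent oracles.

# Maximal runs on one chromosome by per-start scanning: for every start
# index, the largest window free of oversized gaps; keep windows that are
# large enough and cannot be extended on either side.
oracle_clusters_chr <- function(bp, min_size, max_gap) {
  n <- length(bp)
  if (n == 0) return(matrix(numeric(), ncol = 2))
  bad <- which(diff(bp) > max_gap) # gap after index `bad`
  out <- list()
  for (i in seq_len(n)) {
    nb <- bad[bad >= i]
    j <- if (length(nb)) min(nb) else n
    if (j - i + 1 < min_size) next
    left_extendable <- i > 1 && !((i - 1) %in% bad)
    if (left_extendable) next
    out[[length(out) + 1]] <- c(bp[i], bp[j], j - i + 1)
  }
  do.call(rbind, out)
}

oracle_find_clusters <- function(nominal, params) {
  out <- list()
  for (ch in unique(nominal$chr)) {
    bp <- nominal$bp[nominal$chr == ch]
    m <- oracle_clusters_chr(bp, params$min_cluster_size, params$max_gap)
    if (!is.null(m) && nrow(m)) {
      out[[length(out) + 1]] <- data.frame(
        chr = ch, start = m[, 1], end = m[, 2], n_snps = m[, 3],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chr = character(), start = numeric(),
                      end = numeric(), n_snps = numeric()))
  }
  do.call(rbind, out)
}

# All intersecting (a, b) region pairs by quadratic outer comparison.
oracle_overlap_pairs <- function(ra, rb) {
  if (nrow(ra) == 0 || nrow(rb) == 0) {
    return(data.frame(a = integer(), b = integer()))
  }
  hit <- outer(ra$chr, rb$chr, "==") &
    outer(ra$start, rb$end, "<=") &
    outer(ra$end, rb$start, ">=")
  idx <- which(hit, arr.ind = TRUE)
  out <- data.frame(a = idx[, 1], b = idx[, 2])
  out[order(out$a, out$b), , drop = FALSE]
}

# Merged components of pairwise intersections by union-find over a
# quadratic comparison of the intersection intervals.
oracle_merged_overlap_count <- function(ra, rb) {
  pr <- oracle_overlap_pairs(ra, rb)
  if (nrow(pr) == 0) return(0L)
  chr <- ra$chr[pr$a]
  s <- pmax(ra$start[pr$a], rb$start[pr$b])
  e <- pmin(ra$end[pr$a], rb$end[pr$b])
  n <- length(s)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && chr[i] == chr[j] && s[i] <= e[j] && s[j] <= e[i]) {
        parent[find(i)] <- find(j)
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Linear scan annotation oracle under the exon+flank (or gene-body) rule.
oracle_annotate <- function(region, genes, flank, gene_body = FALSE) {
  hits <- character()
  for (i in seq_len(nrow(genes))) {
    if (genes$chr[i] != region$chr) next
    if (gene_body) {
      s <- max(1, genes$tx_start[i] - flank)
      e <- genes$tx_end[i] + flank
      iv_s <- s
      iv_e <- e
    } else {
      iv_s <- c(genes$exon_starts[[i]],
                max(1, genes$tx_start[i] - flank), genes$tx_end[i] + 1)
      iv_e <- c(genes$exon_ends[[i]],
                genes$tx_start[i] - 1, genes$tx_end[i] + flank)
    }
    ok <- iv_s <= iv_e & iv_s <= region$end & iv_e >= region$start
    if (any(ok)) hits <- c(hits, genes$symbol[i])
  }
  sort(unique(hits))
}

# Random sorted significant-SNP tables spread over a few chromosomes, with
# clumpy spacing so clusters of all sizes occur.
random_nominal <- function(n, n_chrom = 3, alpha = 0.05) {
  chr <- sort(sample(as.character(seq_len(n_chrom)), n, replace = TRUE))
  bp <- unlist(lapply(split(seq_len(n), chr), function(idx) {
    gaps <- sample(c(1:5000, 9995:10005, 15000:30000),
                   length(idx), replace = TRUE)
    cumsum(gaps)
  }), use.names = FALSE)
  df <- data.frame(chr = chr, snp = sprintf("rs%d", seq_len(n)), bp = bp,
                   p = runif(n, 0, alpha * 0.999), stringsAsFactors = FALSE)
  df[order(match(df$chr, as.character(seq_len(n_chrom))), df$bp), ]
}

# Random sorted, disjoint region sets.
random_regions <- function(n, n_chrom = 2, span = 1e6) {
  chr <- sort(sample(as.character(seq_len(n_chrom)), n, replace = TRUE))
  out <- lapply(split(seq_len(n), chr), function(idx) {
    k <- length(idx)
    s <- sort(sample.int(span, k))
    len <- sample(c(0:3, 10:5000), k, replace = TRUE)
    e <- s + len
    # enforce disjointness by pushing each region past its predecessor
    for (i in seq_len(k)[-1]) {
      if (s[i] <= e[i - 1]) {
        s[i] <- e[i - 1] + 1 + sample(0:10, 1)
        e[i] <- s[i] + len[i]
      }
    }
    data.frame(chr = chr[idx][1], start = s, end = e,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df$n_snps <- sample(4:10, nrow(df), replace = TRUE)
  df$min_p <- runif(nrow(df), 0, 0.05)
  df$min_p_snp <- sprintf("rs%d", seq_len(nrow(df)))
  df
}

# Random gene-model tables.
random_genes <- function(n, n_chrom = 2, span = 1e6) {
  rows <- lapply(seq_len(n), function(i) {
    len <- sample(2000:50000, 1)
    s <- sample.int(span - len, 1)
    e <- s + len
    n_ex <- sample(1:5, 1)
    if (n_ex > 1) {
      b <- sort(sample((s + 1):(e - 1), 2 * (n_ex - 1)))
      ex_s <- c(s, b[seq(2, length(b), by = 2)] + 1)
      ex_e <- c(b[seq(1, length(b), by = 2)], e)
    } else {
      ex_s <- s
      ex_e <- e
    }
    df <- data.frame(symbol = sprintf("G%03d", i),
                     chr = as.character(sample.int(n_chrom, 1)),
                     strand = sample(c("+", "-"), 1),
                     tx_start = s, tx_end = e, stringsAsFactors = FALSE)
    df$exon_starts <- list(ex_s)
    df$exon_ends <- list(ex_e)
    df
  })
  gene_models(do.call(rbind, rows))
}

# 99% two-sided binomial band around rate p0 for n trials.
binom_band99 <- function(p0, n) {
  half <- stats::qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
  c(p0 - half, p0 + half)
}
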