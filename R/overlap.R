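# Cross-sample replication: intersect the cluster-tagged regions of two
# independent samples, merge connected intersections, and summarize the
# genome-fraction enrichment over the chance expectation.

check_regions_sorted_disjoint <- function(regions, what) {
  if (nrow(regions) < 2) return(invisible(TRUE))
  chr <- as.character(regions$chr)
  if (!is_position_sorted(chr, regions$start)) {
    stop(what, " must be sorted by (chromosome, position)", call. = FALSE)
  }
  same <- chr[-1] == chr[-length(chr)]
  if (any(same & regions$start[-1] <= regions$end[-nrow(regions)])) {
    stop(what, " must be disjoint within each chromosome", call. = FALSE)
  }
  invisible(TRUE)
}

empty_overlaps <- function() {
  out <- data.frame(chr = character(), start = numeric(), end = numeric(),
                    n_pairs = integer(), stringsAsFactors = FALSE)
  out$sources_a <- list()
  out$sources_b <- list()
  attr(out, "pairs") <- data.frame(a = integer(), b = integer(),
                                   component = integer())
  out
}

#' Regions tagged by clusters in both of two samples
#'
#' Finds every pair of intersecting regions (one from each sample), takes
#' the pairwise intersection intervals, and merges intersections that share
#' at least one base into connected components - one overlap region per
#' component. A component's interval is the union of its member
#' intersections. The full pair list is kept in `attr(, "pairs")`, since one
#' region in sample A can intersect several regions in sample B.
#'
#' @param regions_a,regions_b region data frames from [find_clusters()]
#'   (sorted, disjoint within each sample). Coordinates 1-based, closed;
#'   regions touching at a single base count as overlapping.
#' @return data frame of merged overlap regions: `chr`, `start`, `end`,
#'   `n_pairs`, list-columns `sources_a`/`sources_b` (row indices into the
#'   inputs); pair table in `attr(, "pairs")`.
#' @export
overlap_regions <- function(regions_a, regions_b) {
  check_regions_sorted_disjoint(regions_a, "regions_a")
  check_regions_sorted_disjoint(regions_b, "regions_b")
  if (nrow(regions_a) == 0 || nrow(regions_b) == 0) return(empty_overlaps())
  chr_a <- norm_chrom(regions_a$chr)
  chr_b <- norm_chrom(regions_b$chr)
  chrs <- intersect(unique(chr_a), unique(chr_b))
  chrs <- chrs[order(match(chrs, chrom_levels(c(chr_a, chr_b))))]
  rows <- list()
  pairs <- list()
  comp_off <- 0L
  for (ch in chrs) {
    ia <- which(chr_a == ch)
    ib <- which(chr_b == ch)
    ra <- IRanges::IRanges(start = regions_a$start[ia],
                           end = regions_a$end[ia])
    rb <- IRanges::IRanges(start = regions_b$start[ib],
                           end = regions_b$end[ib])
    hits <- IRanges::findOverlaps(ra, rb)
    if (length(hits) == 0) next
    qa <- S4Vectors::queryHits(hits)
    qb <- S4Vectors::subjectHits(hits)
    inter <- IRanges::IRanges(
      start = pmax(regions_a$start[ia][qa], regions_b$start[ib][qb]),
      end = pmin(regions_a$end[ia][qa], regions_b$end[ib][qb]))
    comp <- IRanges::reduce(inter, min.gapwidth = 0L)
    memb <- S4Vectors::subjectHits(IRanges::findOverlaps(inter, comp))
    for (k in seq_along(comp)) {
      sel <- memb == k
      rows[[length(rows) + 1L]] <- data.frame(
        chr = ch, start = IRanges::start(comp)[k],
        end = IRanges::end(comp)[k], n_pairs = sum(sel),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$sources_a <- list(sort(unique(ia[qa[sel]])))
      rows[[length(rows)]]$sources_b <- list(sort(unique(ib[qb[sel]])))
    }
    pairs[[length(pairs) + 1L]] <- data.frame(
      a = ia[qa], b = ib[qb], component = comp_off + memb)
    comp_off <- comp_off + length(comp)
  }
  if (length(rows) == 0) return(empty_overlaps())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pairs") <- do.call(rbind, pairs)
  out
}

#' Genome-fraction enrichment ratio, in percent
#'
#' Ratio of the genome fraction occupied by overlap regions to the fraction
#' expected by chance under independence of the two samples (the product of
#' their clustered genome fractions), expressed as a percent: 100 means
#' exactly the chance expectation.
#'
#' @param fraction_a,fraction_b genome fractions occupied by each sample's
#'   cluster-tagged regions (both must be > 0).
#' @param fraction_overlap genome fraction occupied by the merged overlap
#'   regions.
#' @return percent (numeric scalar).
#' @export
#' @examples
#' enrichment_ratio(0.10, 0.10, 0.021) # 210
enrichment_ratio <- function(fraction_a, fraction_b, fraction_overlap) {
  if (fraction_a <= 0 || fraction_b <= 0) {
    stop("undefined ratio: per-sample genome fractions must be > 0",
         call. = FALSE)
  }
  100 * fraction_overlap / (fraction_a * fraction_b)
}

#' Summarize cross-sample overlap
#'
#' @param regions_a,regions_b per-sample region data frames.
#' @param overlaps output of [overlap_regions()] on the same inputs (computed
#'   here if NULL).
#' @param chrom_sizes named chromosome lengths for genome fractions.
#' @return list of class `overlap_summary`: `n_overlap_regions` (merged
#'   connected components), `n_pairs` (intersecting region pairs),
#'   `fraction_a`, `fraction_b`, `fraction_overlap`, `enrichment_ratio`
#'   (percent). Both counting conventions are reported because published
#'   tables sometimes list one row per pair while prose counts regions.
#' @export
overlap_summary <- function(regions_a, regions_b, overlaps = NULL,
                            chrom_sizes = NULL) {
  if (is.null(overlaps)) overlaps <- overlap_regions(regions_a, regions_b)
  out <- list(n_overlap_regions = nrow(overlaps),
              n_pairs = sum(overlaps$n_pairs),
              fraction_a = NA_real_, fraction_b = NA_real_,
              fraction_overlap = NA_real_, enrichment_ratio = NA_real_)
  if (!is.null(chrom_sizes)) {
    out$fraction_a <- genome_fraction(regions_a, chrom_sizes)
    out$fraction_b <- genome_fraction(regions_b, chrom_sizes)
    out$fraction_overlap <- genome_fraction(overlaps, chrom_sizes)
    if (out$fraction_a > 0 && out$fraction_b > 0) {
      out$enrichment_ratio <- enrichment_ratio(out$fraction_a, out$fraction_b,
                                               out$fraction_overlap)
    }
  }
  structure(out, class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("%d merged overlap regions (%d intersecting pairs)\n",
              x$n_overlap_regions, x$n_pairs))
  if (!is.na(x$fraction_overlap)) {
    cat(sprintf(
      "genome fractions: A %.4g, B %.4g, overlap %.4g (%.0f%% of chance)\n",
      x$fraction_a, x$fraction_b, x$fraction_overlap, x$enrichment_ratio))
  }
  invisible(x)
}

#' Genes identified in every one of several samples or sample pairs
#'
#' Normalizes gene symbols (upper-case, whitespace trimmed, comma-separated
#' multi-gene cells split) and intersects across all inputs.
#'
#' @param ... two or more character vectors of gene symbols; elements may be
#'   comma-separated lists as found in report tables.
#' @return sorted character vector, the intersection of all inputs.
#' @export
#' @examples
#' cross_population_genes(c("CDH13", "A2M,PZP"), c("cdh13", "PZP"))
cross_population_genes <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  if (length(sets) < 2) {
    stop("need at least two gene sets to intersect", call. = FALSE)
  }
  norm <- lapply(sets, function(g) {
    g <- unlist(strsplit(as.character(g), ",", fixed = TRUE))
    g <- toupper(trimws(g))
    unique(g[!is.na(g) & nzchar(g)])
  })
  sort(Reduce(intersect, norm))
}
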