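# Gene annotation under the exon-or-flank rule: a region is assigned to a
# gene when it intersects an exon of the gene or lies within `flank` bp of
# either transcript end. Intron-only overlaps do not count under the literal
# rule; a gene-body mode treating [tx_start - flank, tx_end + flank] as one
# interval is available for coarser labeling.

#' Construct a validated gene-model table
#'
#' One row per gene symbol. Multiple transcripts of one symbol should be
#' pre-merged (union of exons, outermost bounds); [read_gene_models()] does
#' this on import.
#'
#' @param genes data frame with columns `symbol`, `chr`, `strand`,
#'   `tx_start`, `tx_end` and list-columns `exon_starts`, `exon_ends`
#'   (1-based, closed, sorted, non-overlapping, inside the transcript).
#' @return the validated data frame, class `gene_models`.
#' @export
gene_models <- function(genes) {
  need <- c("symbol", "chr", "strand", "tx_start", "tx_end",
            "exon_starts", "exon_ends")
  miss <- setdiff(need, names(genes))
  if (length(miss)) {
    stop("gene table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  genes$chr <- norm_chrom(genes$chr)
  if (anyDuplicated(genes$symbol)) {
    stop("one row per gene symbol required (merge transcripts first)",
         call. = FALSE)
  }
  for (i in seq_len(nrow(genes))) {
    s <- genes$exon_starts[[i]]
    e <- genes$exon_ends[[i]]
    ok <- length(s) == length(e) && length(s) >= 1 &&
      all(s <= e) && !is.unsorted(s, strictly = TRUE) &&
      all(s[-1] > e[-length(e)]) &&
      genes$tx_start[i] <= genes$tx_end[i] &&
      all(s >= genes$tx_start[i]) && all(e <= genes$tx_end[i])
    if (!ok) {
      stop("invalid gene model for ", genes$symbol[i],
           ": exons must be sorted, non-overlapping and inside the transcript",
           call. = FALSE)
    }
  }
  class(genes) <- c("gene_models", class(genes))
  genes
}

#' Build an interval index for gene annotation
#'
#' Per gene, indexes its exon intervals plus the 5' flank
#' `[tx_start - flank, tx_start - 1]` and 3' flank
#' `[tx_end + 1, tx_end + flank]` (clipped at the chromosome start; both
#' flanks span `flank` bp, so coordinates suffice regardless of strand).
#' With `gene_body = TRUE` each gene instead contributes the single interval
#' `[tx_start - flank, tx_end + flank]`, so intronic overlaps also annotate.
#'
#' @param genes a [gene_models()] table.
#' @param flank flanking distance in bp (default 10000).
#' @param gene_body use whole-gene-body intervals instead of exon+flank.
#' @return object of class `annotation_index`.
#' @export
build_annotation_index <- function(genes, flank = 10000, gene_body = FALSE) {
  genes <- gene_models(as.data.frame(genes))
  starts <- vector("list", nrow(genes))
  ends <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    if (gene_body) {
      s <- genes$tx_start[i] - flank
      e <- genes$tx_end[i] + flank
    } else {
      s <- c(genes$exon_starts[[i]],
             genes$tx_start[i] - flank, genes$tx_end[i] + 1)
      e <- c(genes$exon_ends[[i]],
             genes$tx_start[i] - 1, genes$tx_end[i] + flank)
    }
    s <- pmax(s, 1)
    keep <- s <= e
    starts[[i]] <- s[keep]
    ends[[i]] <- e[keep]
  }
  n_iv <- lengths(starts)
  iv_chr <- rep.int(genes$chr, n_iv)
  iv_sym <- rep.int(genes$symbol, n_iv)
  by_chr <- lapply(split(seq_along(iv_chr), iv_chr), function(idx) {
    list(ir = IRanges::IRanges(start = unlist(starts)[idx],
                               end = unlist(ends)[idx]),
         symbol = iv_sym[idx])
  })
  structure(list(by_chr = by_chr, flank = flank, gene_body = gene_body,
                 genes = genes$symbol),
            class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("annotation_index: %d gene(s), flank %g bp, %s rule\n",
              length(x$genes), x$flank,
              if (x$gene_body) "gene-body" else "exon+flank"))
  invisible(x)
}

#' Annotate a region with genes
#'
#' Returns the symbols of all genes whose indexed intervals intersect the
#' region's closed interval, alphabetically sorted. A chromosome absent from
#' the index yields an empty set.
#'
#' @param region a list or one-row data frame with `chr`, `start`, `end`.
#' @param index an [build_annotation_index()] object.
#' @return character vector of gene symbols (possibly empty).
#' @export
annotate_region <- function(region, index) {
  stopifnot(inherits(index, "annotation_index"))
  ch <- norm_chrom(region$chr[[1]])
  slot <- index$by_chr[[ch]]
  if (is.null(slot)) return(character())
  q <- IRanges::IRanges(start = as.numeric(region$start[[1]]),
                        end = as.numeric(region$end[[1]]))
  hits <- IRanges::findOverlaps(q, slot$ir)
  sort(unique(slot$symbol[S4Vectors::subjectHits(hits)]))
}

#' Annotate every region in a table
#'
#' @param regions region or overlap-region data frame (`chr`, `start`, `end`).
#' @param index an [build_annotation_index()] object.
#' @return `regions` with a list-column `genes` of sorted symbol vectors.
#' @export
annotate_regions <- function(regions, index) {
  regions$genes <- lapply(seq_len(nrow(regions)), function(i) {
    annotate_region(regions[i, , drop = FALSE], index)
  })
  regions
}
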