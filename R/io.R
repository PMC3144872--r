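# File formats. Coordinates are 1-based closed in all TSV reports and
# converted centrally to 0-based half-open for BED output. Chromosome labels
# are normalized on ingest ("chr1" -> "1").

bad_rows_msg <- function(path, rows, what) {
  stop(sprintf("%s: line %s: %s", path,
               paste(utils::head(rows + 1L, 5), collapse = ", "), what),
       call. = FALSE)
}

#' Read a SNP association table
#'
#' Tab-separated with header columns CHR, SNP, BP, P (PLINK .assoc-style)
#' and optional MAF and F_MISS. Malformed rows are rejected with their line
#' numbers.
#'
#' @param path file path.
#' @return data frame with columns `chr`, `snp`, `bp`, `p` and, when
#'   present in the file, `maf`, `f_miss`.
#' @export
read_assoc_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("CHR", "SNP", "BP", "P")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(chr = norm_chrom(raw$CHR), snp = as.character(raw$SNP),
                    bp = as.numeric(raw$BP), p = as.numeric(raw$P),
                    stringsAsFactors = FALSE)
  if ("MAF" %in% names(raw)) out$maf <- as.numeric(raw$MAF)
  if ("F_MISS" %in% names(raw)) out$f_miss <- as.numeric(raw$F_MISS)
  bad <- which(is.na(out$bp) | out$bp < 1)
  if (length(bad)) bad_rows_msg(path, bad, "invalid BP")
  bad <- which(!is.na(out$p) & (out$p < 0 | out$p > 1))
  if (length(bad)) bad_rows_msg(path, bad, "P outside [0, 1]")
  check_snp_table(out, require_p = TRUE, what = path)
  out
}

#' Write a SNP association table
#'
#' @param snps data frame with `chr`, `snp`, `bp`, `p` (and optionally
#'   `maf`, `f_miss`).
#' @param path output path (tab-separated, header CHR SNP BP P ...).
#' @export
write_assoc_table <- function(snps, path) {
  out <- data.frame(CHR = snps$chr, SNP = snps$snp, BP = snps$bp, P = snps$p)
  if ("maf" %in% names(snps)) out$MAF <- snps$maf
  if ("f_miss" %in% names(snps)) out$F_MISS <- snps$f_miss
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pooled allele-frequency table
#'
#' Tab-separated, one row per SNP: CHR, SNP, BP, then one column per pool
#' named CASE1..CASEk and CTRL1..CTRLm.
#'
#' @param path file path.
#' @return list with `snps` (data frame `chr`, `snp`, `bp`), `case` and
#'   `control` (numeric matrices, one column per pool).
#' @export
read_pool_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("CHR", "SNP", "BP")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  case_cols <- grep("^CASE[0-9]+$", names(raw), value = TRUE)
  ctrl_cols <- grep("^CTRL[0-9]+$", names(raw), value = TRUE)
  if (length(case_cols) < 2 || length(ctrl_cols) < 2) {
    stop(path, ": need at least 2 CASE<i> and 2 CTRL<i> pool columns",
         call. = FALSE)
  }
  est <- as.matrix(raw[c(case_cols, ctrl_cols)])
  bad <- which(apply(est, 1, function(r) any(is.na(r) | r < 0 | r > 1)))
  if (length(bad)) bad_rows_msg(path, bad, "pool estimate outside [0, 1]")
  list(snps = data.frame(chr = norm_chrom(raw$CHR),
                         snp = as.character(raw$SNP),
                         bp = as.numeric(raw$BP), stringsAsFactors = FALSE),
       case = as.matrix(raw[case_cols]),
       control = as.matrix(raw[ctrl_cols]))
}

#' Write per-sample regions as a report table
#'
#' Tab-separated with the half-row layout of a published cluster table:
#' `ch`, `n_snps`, `bp_start`, `bp_end`, `pmin_snp`, `pmin`.
#'
#' @param regions region data frame from [find_clusters()].
#' @param path output path.
#' @export
write_region_table <- function(regions, path) {
  out <- data.frame(ch = regions$chr, n_snps = regions$n_snps,
                    bp_start = regions$start, bp_end = regions$end,
                    pmin_snp = regions$min_p_snp, pmin = regions$min_p)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a region report table written by [write_region_table()]
#'
#' @param path file path.
#' @return region data frame (`chr`, `start`, `end`, `n_snps`, `min_p`,
#'   `min_p_snp`).
#' @export
read_region_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(chr = norm_chrom(raw$ch), start = as.numeric(raw$bp_start),
             end = as.numeric(raw$bp_end), n_snps = as.integer(raw$n_snps),
             min_p = as.numeric(raw$pmin), min_p_snp = raw$pmin_snp,
             stringsAsFactors = FALSE)
}

#' Write regions or overlap regions as BED
#'
#' Converts from internal 1-based closed coordinates to BED's 0-based
#' half-open. For cluster regions writes BED3+ with name = `min_p_snp`,
#' score = -log10(min p), and `n_snps`; for overlap regions name/score are
#' generic.
#'
#' @param regions region or overlap-region data frame.
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  n <- nrow(regions)
  if ("min_p" %in% names(regions)) {
    name <- regions$min_p_snp
    score <- round(-log10(regions$min_p), 4)
    extra <- regions$n_snps
  } else {
    name <- sprintf("overlap_%d", seq_len(n))
    score <- rep.int(0, n)
    extra <- if ("n_pairs" %in% names(regions)) regions$n_pairs
             else rep.int(NA_integer_, n)
  }
  out <- data.frame(chrom = regions$chr, start = regions$start - 1,
                    end = regions$end, name = name, score = score,
                    extra = extra)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a cross-sample overlap report in the published two-half-row layout
#'
#' One row per intersecting (A, B) region pair: `ch`, the A-region half-row
#' (`a_n_snps`, `a_start`, `a_end`, `a_pmin_snp`, `a_pmin`), the matching
#' B-region half-row, and the comma-joined `genes` of the merged overlap
#' component (empty when not annotated).
#'
#' @param overlaps output of [overlap_regions()] (optionally after
#'   [annotate_regions()]).
#' @param regions_a,regions_b the region tables that produced `overlaps`.
#' @param path output path.
#' @export
write_overlap_table <- function(overlaps, regions_a, regions_b, path) {
  pairs <- attr(overlaps, "pairs")
  if (is.null(pairs) || nrow(pairs) == 0) {
    pairs <- data.frame(a = integer(), b = integer(), component = integer())
  }
  genes <- if ("genes" %in% names(overlaps)) {
    vapply(overlaps$genes[pairs$component],
           function(g) paste(g, collapse = ", "), character(1))
  } else {
    rep.int("", nrow(pairs))
  }
  out <- data.frame(
    ch = regions_a$chr[pairs$a],
    a_n_snps = regions_a$n_snps[pairs$a],
    a_start = regions_a$start[pairs$a], a_end = regions_a$end[pairs$a],
    a_pmin_snp = regions_a$min_p_snp[pairs$a],
    a_pmin = regions_a$min_p[pairs$a],
    b_n_snps = regions_b$n_snps[pairs$b],
    b_start = regions_b$start[pairs$b], b_end = regions_b$end[pairs$b],
    b_pmin_snp = regions_b$min_p_snp[pairs$b],
    b_pmin = regions_b$min_p[pairs$b],
    genes = genes, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from BED12 or GFF3
#'
#' BED12 blocks become exons; GFF3 `gene`/`exon` (or `mRNA`) features are
#' grouped by gene. Multiple transcripts per symbol are merged to one model
#' (union of exons, outermost bounds).
#'
#' @param path file path; format inferred from the extension (`.bed` vs
#'   `.gff`/`.gff3`) unless given.
#' @param format "bed" or "gff3".
#' @return a [gene_models()] table.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else "gff3"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    sym <- as.character(gr$name)
    ex <- rtracklayer::blocks(gr)
    rows <- lapply(seq_along(gr), function(i) {
      df <- data.frame(
        symbol = sym[i],
        chr = norm_chrom(as.character(GenomicRanges::seqnames(gr)[i])),
        strand = as.character(GenomicRanges::strand(gr)[i]),
        tx_start = GenomicRanges::start(gr)[i],
        tx_end = GenomicRanges::end(gr)[i], stringsAsFactors = FALSE)
      df$exon_starts <- list(GenomicRanges::start(ex[[i]]))
      df$exon_ends <- list(GenomicRanges::end(ex[[i]]))
      df
    })
    out <- do.call(rbind, rows)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    ex <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(ex) == 0) stop(path, ": no exon features", call. = FALSE)
    sym <- if (!is.null(ex$gene_id)) as.character(ex$gene_id)
           else sub("\\..*$", "", as.character(unlist(ex$Parent)))
    rows <- lapply(split(seq_along(ex), sym), function(idx) {
      r <- IRanges::reduce(IRanges::IRanges(
        start = GenomicRanges::start(ex)[idx],
        end = GenomicRanges::end(ex)[idx]))
      df <- data.frame(
        symbol = sym[idx[1]],
        chr = norm_chrom(as.character(GenomicRanges::seqnames(ex)[idx[1]])),
        strand = as.character(GenomicRanges::strand(ex)[idx[1]]),
        tx_start = min(IRanges::start(r)), tx_end = max(IRanges::end(r)),
        stringsAsFactors = FALSE)
      df$exon_starts <- list(IRanges::start(r))
      df$exon_ends <- list(IRanges::end(r))
      df
    })
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out <- out[chrom_order(out$chr, out$tx_start), , drop = FALSE]
  gene_models(out)
}

#' Write gene models as BED12
#'
#' @param genes a [gene_models()] table.
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    s <- genes$exon_starts[[i]]
    e <- genes$exon_ends[[i]]
    paste(genes$chr[i], genes$tx_start[i] - 1, genes$tx_end[i],
          genes$symbol[i], 0, genes$strand[i],
          genes$tx_start[i] - 1, genes$tx_end[i], "0", length(s),
          paste0(paste(e - s + 1, collapse = ","), ","),
          paste0(paste(s - genes$tx_start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a Monte Carlo result as JSON
#'
#' Emits `null_id`, `observed_stat`, `n_trials`, `n_exceed`, `empirical_p`,
#' `seed` and the scan parameters; trial statistics optionally as a
#' one-column TSV alongside.
#'
#' @param result an `mc_result`.
#' @param path output JSON path.
#' @param trials_path optional TSV path for the full trial statistics.
#' @export
write_mc_json <- function(result, path, trials_path = NULL) {
  out <- list(null_id = result$null_id,
              observed_stat = result$observed_stat,
              n_trials = result$n_trials, n_exceed = result$n_exceed,
              empirical_p = result$empirical_p,
              seed = result$seed,
              params = unclass(result$params))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(trials_path)) {
    write.table(data.frame(trial_stat = result$trial_stats), trials_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
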