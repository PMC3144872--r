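# End-to-end orchestration: two samples in, per-sample cluster regions,
# cross-sample overlap, Monte Carlo significance for both nulls, gene
# annotation, and a reproducible report bundle out.

#' Pipeline configuration
#'
#' @param sample_a,sample_b per-sample inputs: either a list
#'   `list(data = <data frame or path>, type = , label = )` or just the data.
#'   `type` is one of "precomputed_p" (association table with CHR SNP BP P),
#'   "chi2" (genotype-count table for [assoc_from_counts()]) or "pool_t"
#'   (pool table for [assoc_from_pools()]).
#' @param params [scan_params()] for the cluster scan.
#' @param maf_min,missing_max QC thresholds for [filter_snps()]; QC runs
#'   only when `apply_qc` is TRUE.
#' @param apply_qc apply marker QC before the scan.
#' @param n_trials Monte Carlo trials per null (default 10000).
#' @param seed master seed; clustering nulls use `seed + 1` / `seed + 2`,
#'   the overlap null `seed + 3`.
#' @param chrom_sizes named chromosome lengths; when NULL, per-chromosome
#'   maxima of the two maps are used as a proxy (noted in the run log).
#' @param genes gene models: a [gene_models()] table or a BED12/GFF3 path;
#'   NULL skips annotation.
#' @param flank annotation flank in bp.
#' @param gene_body annotate with whole-gene-body intervals.
#' @param autosomes_only restrict the analysis to autosomes.
#' @param out_dir directory for report files; NULL keeps results in memory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_a, sample_b, params = scan_params(),
                            maf_min = 0.01, missing_max = 0.05,
                            apply_qc = FALSE, n_trials = 10000, seed = 1,
                            chrom_sizes = NULL, genes = NULL, flank = 10000,
                            gene_body = FALSE, autosomes_only = TRUE,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

load_sample <- function(spec, default_label) {
  if (is.data.frame(spec)) spec <- list(data = spec)
  type <- spec$type %||% "precomputed_p"
  label <- spec$label %||% default_label
  data <- spec$data
  if (is.character(data)) {
    if (!file.exists(data)) {
      stop("input file not found: ", data, call. = FALSE)
    }
    data <- switch(type,
                   precomputed_p = read_assoc_table(data),
                   chi2 = utils::read.delim(data, stringsAsFactors = FALSE),
                   pool_t = read_pool_table(data),
                   stop("unknown sample type: ", type, call. = FALSE))
  }
  snps <- switch(type,
                 precomputed_p = data,
                 chi2 = assoc_from_counts(data),
                 pool_t = assoc_from_pools(data),
                 stop("unknown sample type: ", type, call. = FALSE))
  snps$chr <- norm_chrom(snps$chr)
  check_snp_table(snps, require_p = TRUE, what = label)
  list(snps = snps, label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full region-replication pipeline on two samples
#'
#' Stages: load/compute per-SNP p-values, optional marker QC, nominal
#' selection, within-sample cluster scan, cross-sample overlap, Monte Carlo
#' clustering null per sample and overlap null for the pair, and gene
#' annotation of the overlap regions. Re-running with an identical
#' configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return list of class `clustrep_result`: `summary_a`/`summary_b`
#'   (assayed/positive/cluster counts and genome fraction), `regions_a`,
#'   `regions_b`, `overlaps`, `overlap_summary`, `mc_clustering_a`,
#'   `mc_clustering_b`, `mc_overlap`, `genes` (cross-sample annotated
#'   symbols), `log`. When `config$out_dir` is set the report files are
#'   written there as TSV/BED/JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) {
    log <<- c(log, sprintf(...))
  }
  a <- load_sample(config$sample_a, "A")
  b <- load_sample(config$sample_b, "B")
  note("samples: %s (%d SNPs), %s (%d SNPs)", a$label, nrow(a$snps),
       b$label, nrow(b$snps))
  if (config$apply_qc) {
    for (nm in c("a", "b")) {
      s <- get(nm)
      f <- filter_snps(s$snps, config$maf_min, config$missing_max)
      note("%s QC: %d retained, %d excluded", s$label, nrow(f$retained),
           nrow(f$excluded))
      s$snps <- f$retained
      s$excluded <- f$excluded
      assign(nm, s)
    }
  }
  params <- config$params
  map_a <- snp_map(a$snps, params$alpha, config$autosomes_only)
  map_b <- snp_map(b$snps, params$alpha, config$autosomes_only)
  nom_a <- select_nominal(a$snps, params$alpha, config$autosomes_only)
  nom_b <- select_nominal(b$snps, params$alpha, config$autosomes_only)
  reg_a <- find_clusters(nom_a, params)
  reg_b <- find_clusters(nom_b, params)
  sizes <- config$chrom_sizes
  if (is.null(sizes)) {
    all_chr <- union(map_a$chr, map_b$chr)
    sizes <- vapply(all_chr, function(ch) {
      max(map_a$bp[map_a$chr == ch], map_b$bp[map_b$chr == ch])
    }, numeric(1))
    note("chrom_sizes not supplied; using per-chromosome marker maxima")
  } else {
    names(sizes) <- norm_chrom(names(sizes))
  }
  summarize <- function(map, nom, reg, label) {
    list(label = label, n_snps_assayed = map$n_total,
         n_nominally_positive = nrow(nom), n_clusters = nrow(reg),
         genome_fraction = genome_fraction(reg, sizes))
  }
  summary_a <- summarize(map_a, nom_a, reg_a, a$label)
  summary_b <- summarize(map_b, nom_b, reg_b, b$label)
  note("%s: %d nominally positive, %d clusters", a$label,
       summary_a$n_nominally_positive, summary_a$n_clusters)
  note("%s: %d nominally positive, %d clusters", b$label,
       summary_b$n_nominally_positive, summary_b$n_clusters)
  overlaps <- overlap_regions(reg_a, reg_b)
  osum <- overlap_summary(reg_a, reg_b, overlaps, sizes)
  note("overlap: %d merged regions, %d pairs", osum$n_overlap_regions,
       osum$n_pairs)
  mc_a <- mc_clustering_null(map_a, params, n_trials = config$n_trials,
                             seed = config$seed + 1)
  mc_b <- mc_clustering_null(map_b, params, n_trials = config$n_trials,
                             seed = config$seed + 2)
  mc_o <- mc_overlap_null(map_a, map_b, params,
                          observed_stat = osum$n_overlap_regions,
                          n_trials = config$n_trials,
                          seed = config$seed + 3)
  note("Monte Carlo (%d trials): clustering p %.4g / %.4g, overlap p %.4g",
       config$n_trials, mc_a$empirical_p, mc_b$empirical_p, mc_o$empirical_p)
  genes <- NULL
  if (!is.null(config$genes)) {
    gm <- if (is.character(config$genes)) read_gene_models(config$genes)
          else gene_models(config$genes)
    idx <- build_annotation_index(gm, config$flank, config$gene_body)
    overlaps <- annotate_regions(overlaps, idx)
    genes <- sort(unique(unlist(overlaps$genes)))
    note("annotation: %d gene(s) over %d overlap regions", length(genes),
         nrow(overlaps))
  }
  result <- structure(list(
    summary_a = summary_a, summary_b = summary_b,
    regions_a = reg_a, regions_b = reg_b,
    overlaps = overlaps, overlap_summary = osum,
    mc_clustering_a = mc_a, mc_clustering_b = mc_b, mc_overlap = mc_o,
    genes = genes, chrom_sizes = sizes, params = params,
    seed = config$seed, log = log), class = "clustrep_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(config$out_dir, f)
    write_region_table(reg_a, fp("regions_a.tsv"))
    write_region_table(reg_b, fp("regions_b.tsv"))
    write_bed(reg_a, fp("regions_a.bed"))
    write_bed(reg_b, fp("regions_b.bed"))
    if (nrow(overlaps)) write_bed(overlaps, fp("overlaps.bed"))
    write_overlap_table(overlaps, reg_a, reg_b, fp("overlap_table.tsv"))
    write_mc_json(mc_a, fp("mc_clustering_a.json"))
    write_mc_json(mc_b, fp("mc_clustering_b.json"))
    write_mc_json(mc_o, fp("mc_overlap.json"), fp("mc_overlap_trials.tsv"))
    writeLines(log, fp("run_log.txt"))
  }
  result
}

#' @export
print.clustrep_result <- function(x, ...) {
  for (s in list(x$summary_a, x$summary_b)) {
    cat(sprintf(
      "%s: %d SNPs assayed, %d nominally positive, %d clusters (%.3g%% of genome)\n",
      s$label, s$n_snps_assayed, s$n_nominally_positive, s$n_clusters,
      100 * s$genome_fraction))
  }
  print(x$overlap_summary)
  cat(sprintf("Monte Carlo clustering p: %.4g (%s), %.4g (%s)\n",
              x$mc_clustering_a$empirical_p, x$summary_a$label,
              x$mc_clustering_b$empirical_p, x$summary_b$label))
  cat(sprintf("Monte Carlo overlap p: %.4g (%d trials)\n",
              x$mc_overlap$empirical_p, x$mc_overlap$n_trials))
  if (!is.null(x$genes)) {
    cat(sprintf("genes over overlap regions: %s\n",
                paste(utils::head(x$genes, 10), collapse = ", ")))
  }
  invisible(x)
}
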