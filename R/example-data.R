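#' Bundled example cross-sample region tables
#'
#' Two published report tables of chromosomal regions identified by clusters
#' of nominally significant SNPs in both of two independent substance- and
#' alcohol-dependence case-control samples: one comparison in
#' European-American subjects (`"ea"`, 119 pair rows) and one in
#' African-American subjects (`"aa"`, 69 pair rows). Each row holds the two
#' samples' half-rows (SNP count, region bounds, minimum-p SNP and p-value)
#' plus the comma-separated gene(s) the region identifies. Useful as real
#' worked input for [cross_population_genes()] and [overlap_regions()].
#'
#' @param which `"ea"` or `"aa"`.
#' @return data frame with columns `ch`, `a_n_snps`, `a_start`, `a_end`,
#'   `a_pmin_snp`, `a_pmin`, `b_n_snps`, `b_start`, `b_end`, `b_pmin_snp`,
#'   `b_pmin`, `genes`.
#' @export
#' @examples
#' ea <- example_overlap_table("ea")
#' aa <- example_overlap_table("aa")
#' cross_population_genes(ea$genes, aa$genes)
example_overlap_table <- function(which = c("ea", "aa")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      sprintf("overlap_regions_%s.tsv", which),
                      package = "clustrep", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
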