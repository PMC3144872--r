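#' Normalize chromosome labels
#'
#' Strips any leading "chr" prefix and upper-cases sex/mitochondrial labels,
#' so "chr1", "Chr1" and "1" all map to "1". Used on ingest everywhere the
#' package accepts chromosome labels.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
#' @examples
#' norm_chrom(c("chr1", "2", "chrX"))
norm_chrom <- function(x) {
  x <- trimws(as.character(x))
  toupper(sub("^[Cc][Hh][Rr]", "", x))
}

#' Test whether a normalized chromosome label is autosomal
#'
#' @param x character vector of normalized chromosome labels.
#' @return logical vector.
#' @export
is_autosome <- function(x) grepl("^[0-9]+$", x)

# Natural chromosome ordering: 1..22, X, Y, MT, then anything else.
chrom_levels <- function(x) {
  u <- unique(as.character(x))
  num <- suppressWarnings(as.numeric(u))
  key <- ifelse(!is.na(num), num, 100 + match(u, c("X", "Y", "M", "MT")))
  key[is.na(key)] <- 200 + seq_len(sum(is.na(key)))
  u[order(key)]
}

chrom_order <- function(chr, bp) {
  order(match(chr, chrom_levels(chr)), bp)
}

# Validate a SNP association table (chr, snp, bp, and optionally p, maf,
# f_miss columns). Stops with an informative message on the first violation.
check_snp_table <- function(snps, require_p = FALSE, what = "snps") {
  if (!is.data.frame(snps)) {
    stop(what, " must be a data frame", call. = FALSE)
  }
  need <- c("chr", "snp", "bp")
  if (require_p) need <- c(need, "p")
  miss <- setdiff(need, names(snps))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(snps) == 0) return(invisible(snps))
  if (any(snps$bp < 1)) stop("positions must be >= 1 (1-based)", call. = FALSE)
  if (anyDuplicated(snps$snp)) {
    stop("duplicated SNP ids: ",
         paste(utils::head(unique(snps$snp[duplicated(snps$snp)]), 3),
               collapse = ", "), call. = FALSE)
  }
  if ("p" %in% names(snps) && any(!is.na(snps$p) &
                                  (snps$p < 0 | snps$p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if ("maf" %in% names(snps) && any(!is.na(snps$maf) &
                                    (snps$maf < 0 | snps$maf > 0.5))) {
    stop("minor-allele frequencies must lie in [0, 0.5]", call. = FALSE)
  }
  invisible(snps)
}

# Check that a SNP table is sorted: chromosomes in contiguous blocks with
# non-decreasing positions inside each block.
is_position_sorted <- function(chr, bp) {
  n <- length(chr)
  if (n < 2) return(TRUE)
  new_chr <- chr[-1] != chr[-n]
  if (anyDuplicated(c(chr[1], chr[-1][new_chr]))) return(FALSE)
  all(new_chr | diff(bp) >= 0)
}

# Encode (chr, bp) into a single numeric key so that positions on different
# chromosomes are always further apart than any gap threshold. `levels` and
# `offset` must be shared between maps that will be compared.
encode_keys <- function(chr, bp, levels, offset) {
  (match(chr, levels) - 1) * offset + bp
}
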