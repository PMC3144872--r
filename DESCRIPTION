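Package: clustrep
Title: Region-Based Replication of GWAS Signals from Clusters of
    Nominally Significant SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects chromosomal regions tagged by clusters of nominally
    significant SNPs (p < 0.05) in each of several independent case-control
    GWAS samples, identifies regions replicated across samples by interval
    overlap, assigns empirical significance to clustering and cross-sample
    overlap by Monte Carlo resampling of "pseudo-positive" markers from each
    platform's SNP map, and annotates replicated regions with genes using an
    exon-or-flank rule. Per-SNP association tests for individual genotyping
    (allelic chi-square) and pooled-DNA designs (multi-pool t-test) are
    included, together with a synthetic dual-platform data generator with
    planted risk regions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
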