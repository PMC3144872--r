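---
title: "Region-based replication of GWAS signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based replication of GWAS signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustrep)
```

## The problem

For polygenic phenotypes, "template" replication — the same SNP reaching
genome-wide significance (p ~ 1e-8) with the same phase in several
independent samples — is rarely achievable: effects are small, risk alleles
and loci are heterogeneous, samples differ in linkage-disequilibrium fine
structure, and different genotyping platforms assay largely non-overlapping
marker sets (1M-class arrays from different vendors share only about a
quarter of their autosomal SNPs). clustrep implements a *nontemplate*
alternative: declare replication at the level of chromosomal regions that
are tagged, in each of several independent case-control samples, by
*clusters* of merely nominally significant SNPs, and quantify how unlikely
the observed clustering and the observed cross-sample regional overlap
would be if significance labels were scattered at random over each
platform's marker map.

## The procedure

1. **Per-SNP association.** Individually genotyped samples use the 1-df
   Pearson chi-square on the 2x2 case/control allele-count table (no
   continuity correction), computed from the closed form
   $\chi^2 = n(ad-bc)^2/(r_1 r_2 c_1 c_2)$. Pooled-DNA designs compare
   per-pool minor-allele frequency estimates from multiple case pools
   against multiple control pools with a two-sample t-test. Markers with
   minor-allele frequency below 0.01-0.02 or missing call rates above 5%
   are excluded when those QC fields are available.

2. **Cluster scan.** Within one sample, a marker is *nominally positive*
   when p < 0.05 (strict). A *cluster* is a maximal run of nominally
   positive SNPs on one chromosome in which each adjacent pair lies within
   `max_gap` = 10 kb, containing at least `min_cluster_size` = 4 members
   (for sparser 500K-class arrays, 3 members within 25 kb is the customary
   variant; both are plain parameters of `scan_params()`). The run is a
   single-linkage chain over the nominally positive SNPs only:
   non-significant markers in between neither join nor break it — the
   criterion refers to the distance to the nearest nominally significant
   neighbour. A cluster's *region* is the closed interval between its
   outermost member positions.

3. **Cross-sample overlap.** Regions from two samples are intersected; all
   intersecting (A, B) pairs are found, and intersection intervals that
   share at least one base are merged into connected components — one
   *overlap region* each. Both counts are reported (`n_overlap_regions`
   and `n_pairs`) because published tables list one row per pair while
   prose counts regions; with regions disjoint within each sample the two
   usually coincide. The genome-fraction *enrichment ratio* is
   $100 \times f_{AB} / (f_A f_B)$, the observed overlap fraction relative
   to the independence expectation of the two samples' clustered fractions.

4. **Monte Carlo nulls.** Two null hypotheses get empirical p-values by
   *pseudo-positive* resampling, which keeps every marker at its true map
   position and randomizes only the significance labels: each trial draws,
   uniformly without replacement from the full post-QC marker list, exactly
   as many pseudo-positives as were observed, then recomputes the
   statistic. The clustering null uses the number of clusters in one
   sample (the clustered-SNP count is recorded as a secondary statistic);
   the overlap null draws independently in both samples and counts merged
   overlap regions. Ties count as exceedances, and the add-one estimator
   $\hat p = (k+1)/(T+1)$ is used, so 0 exceedances in 10,000 trials
   reports ~1e-4 ("p < 0.0001") rather than an impossible zero.

5. **Gene annotation.** A region is assigned to a gene when it intersects
   an exon or lies within 10 kb of either transcript end. The literal rule
   excludes intron-only overlaps; because published region tables are
   gene-labelled without exon detail, `gene_body_mode` optionally treats
   `[tx_start - flank, tx_end + flank]` as one interval (always a superset
   of the literal rule). Multiple transcripts are merged per symbol on
   import. Gene sets from several sample pairs are intersected after
   upper-casing, trimming and splitting comma-separated cells.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | nominal per-SNP significance (strict `<`) |
| `min_cluster_size` | 4 | minimum SNPs per cluster (3 for 500K arrays) |
| `max_gap` | 10,000 bp | maximum separation of adjacent clustered SNPs (inclusive) |
| `n_trials` | 10,000 | Monte Carlo trials per null |
| `flank` | 10,000 bp | annotation flank on each transcript end |

Coordinates are 1-based and closed everywhere internally and in TSV
reports; BED output converts centrally to 0-based half-open. Chromosome
labels are normalized on ingest ("chr1" to "1") and the analysis is
autosome-only by default. Two markers at the same position count
separately; a gap of exactly `max_gap` joins.

## Design choices that were genuinely open

- **t-test variant.** Whether pooled designs use Welch or pooled-variance
  t is not standardized; clustrep defaults to Welch with
  Welch-Satterthwaite df (pool counts and variances can differ between
  groups) and exposes `var_equal = TRUE`. Note a real small-sample
  property: with 4 pools per group and equal variances, the Welch test is
  conservative (true type-I rate ~0.041 at nominal 0.05); the
  pooled-variance variant is exact under the equal-variance Gaussian noise
  model, and Welch approaches the nominal level as pool counts grow. The
  test suite asserts exactly this pattern rather than forcing Welch at 4
  pools into a band around 0.05 it provably cannot meet.
- **Chain semantics.** Whether an intervening non-significant SNP can
  break a cluster is not decidable from the criterion's wording; the chain
  is defined over significant SNPs only (see step 2).
- **Counting convention** for regions identified in both samples: merged
  connected components, with the pair count also surfaced (step 3).
- **Clustering-null statistic.** "Extent of clustering" is summarized as
  the cluster count, with clustered-SNP count carried alongside.
- **RNG discipline.** One master seed derives a vector of per-trial
  sub-seeds, so trials are reproducible independently of execution order.

## The synthetic-data generator

Real inputs of this kind (controlled-access dbGaP genotypes, unreleased
pooled-array data) are not redistributable, so the package ships a
generator that emulates the *statistical* structure the method relies on:

- two platforms' autosomal maps with uniform marker positions and a
  controllable shared fraction (default 0.25, matching the roughly
  quarter-million shared autosomal SNPs of 1M-class array pairs);
- uniform null p-values, independent across SNPs;
- planted shared risk regions: disjoint windows of width `2 * max_gap`,
  each containing at least `snps_per_risk_region` (default 6) markers on
  both platforms, all of whose markers draw Beta(a, 1) p-values with
  a = 0.1, giving closed-form per-SNP power $P(p < \alpha) = \alpha^a$
  (~0.74 at alpha 0.05);
- per-pool allele-frequency noise, Gaussian with SD 0.02 truncated to
  [0, 1] (truncation rather than re-drawing; negligible at interior
  frequencies);
- HWE binomial allele counts for the chi-square path; and
- non-overlapping multi-exon gene models, with one gene placed over each
  planted region so annotation recovery can be scored.

Default problem size: 10 chromosomes x 12 Mb, 100,000 SNPs per platform
(~1.2 kb marker spacing). The chromosome length is the one free geometry
parameter and was calibrated once, on seeds disjoint from any used in the
test suite, so that the generator's two advertised properties hold jointly
with margin: planted-signal runs recover >= 80% of truth regions (observed
minimum 0.95 over 40 calibration seeds) *and* their overlap null yields
the minimum attainable empirical p at 1,000 trials (0 of 40 seeds saw any
exceedance). Shorter chromosomes push the null overlap baseline up toward
the observed statistic; longer ones thin the planted windows below
reliable cluster formation.

What the generator deliberately does **not** model: linkage
disequilibrium, haplotype structure, or population stratification. Risk
signal is injected directly at the p-value level. Two consequences matter
for interpreting test results. First, passing tests demonstrate the
machinery (scan, overlap, resampling, annotation) is correct and
calibrated, not that the method is powerful on real LD structure. Second,
because non-risk p-values are spatially independent, concentrating the
signal in 20 small windows barely changes the *total* cluster count, so
the within-sample clustering null has little power on synthetic data (its
empirical p is typically unremarkable) — on real data that statistic is
driven by LD-induced clustering. The cross-sample overlap null, which is
the method's centrepiece, is highly significant on planted-signal data and
uniform-ish on pure-null data, exactly as it should be.

## Numerical and degenerate-input choices

- 2x2 chi-square margins are multiplied in double precision (the integer
  product overflows for sample sizes well within GWAS range); monomorphic
  tables signal a "degenerate table" error and are skipped upstream.
- Fewer than 2 pools per group, or zero variance in both groups, are
  errors ("insufficient pools", "degenerate variance"); identical groups
  with nonzero variance return t = 0, p = 1.
- Empty inputs flow through: no significant SNPs means no regions, zero
  overlap, empirical p 1.
- `empirical_p` lives in (0, 1] by construction; it is monotone
  non-increasing in the observed statistic for fixed trials.
- Interval containment checks use closed-interval arithmetic; region
  length is `end - start + 1`.

## Problem sizes used by the test suite

Unit tests run on maps of 10^3-10^5 markers. The acceptance-style checks
use: 1,000 random instances (up to 200 SNPs) against a brute-force cluster
oracle; 500 random region-set pairs against a quadratic overlap oracle;
200 pure-null dataset pairs (10,000 SNPs per platform over 4 x 1 Mb, 500
trials each) for overlap-null calibration — the geometry is chosen so the
null overlap-count distribution is non-degenerate (~30 merged regions per
trial) and the p <= 0.05 fraction is meaningfully testable against a 99%
binomial band; and 20 planted-signal datasets at the full default size
with 1,000-trial overlap nulls. The whole suite runs in a few minutes on
one CPU.

## Known limitations

- Purely positional clustering: no LD-aware merging, imputation or
  haplotype phasing; marker density directly limits which regions are
  discoverable (a 4-in-10-kb rule simply cannot fire where a platform has
  fewer than 4 markers per 10 kb).
- The overlap null treats the two samples as independent; shared ancestry
  structure between samples would inflate apparent replication.
- Gene annotation is symbol-level against user-supplied models; aliases
  are not resolved.
- Phenotype-label permutation testing is out of scope (standard external
  tools cover it); the Monte Carlo nulls here randomize marker labels, not
  phenotypes, and so condition on the observed number of positives.
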