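---
title: "Methods: eRNA cis-QTL mapping on synthetic cohorts"
author: "ernaqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eRNA cis-QTL mapping on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernaqtl)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what its synthetic benchmarks do and do
not demonstrate.

## The pipeline and its assumptions

The analysis chain is: replicate chromatin peaks → active enhancers → eRNA
regions → RPKM matrix → detectable eRNAs → normal scores → covariate-adjusted
cis-QTL scan with Storey FDR → condition specificity, enrichment, target
genes, and case-control association. The statistical core assumes an
additive allelic effect on rank-normalized eRNA abundance, linear covariate
confounding, and exchangeable samples; the FDR machinery assumes p-values
that are uniform under the null, which holds exactly for the OLS t-test when
residuals are i.i.d. normal and approximately otherwise after the
inverse-normal transform.

## Coordinates and interval arithmetic

All coordinates are 0-based half-open (BED convention); GTF input is shifted
on read. Abutting intervals merge, because every downstream rule (replicate
support, assay confirmation, exclusion zones) is a statement about *covered
bases*, not about peak identity. Two consequences are worth stating
explicitly:

* "supported by at least two samples" is resolved per base on the union of
  each sample's merged peaks, then trimmed to the supported segments. This
  makes the enhancer set invariant to sample order and robust to boundary
  jitter, at the cost of occasionally splitting a ragged peak into two
  supported segments.
* a candidate enhancer is removed outright on *any* overlap with a TSS ±2.5 kb
  window (no trimming), and an eRNA region on any overlap with a
  protein-coding gene extended by 1 kb — elements are excluded, not clipped.

The assay intersection reports the accessibility (ATAC) interval by default:
accessibility defines the element boundary and H3K27ac confirms activity.
Since the kept interval is not uniquely determined by the published rule,
`candidate_enhancers(report = "overlap")` switches to the overlap segment.

## Quantification choices

eRNA regions are midpoint ±3 kb (`half_width = 3000`), deliberately *not*
merged when they overlap — one region per enhancer — with duplicates
deduplicated. A read overlapping k regions counts in all k by default
(`multi_count = "all"`); the `"fractional"` policy (1/k each) is available
when double counting matters. Library size is the total mapped reads of the
sample, not reads-in-regions, matching the RPKM denominator. Detectability
uses a strict "more than 50% of samples" inequality: a feature expressed in
exactly half the samples is removed.

"Quantile normalization" for QTL mapping is implemented as the per-feature
rank-based inverse-normal transform with the Blom offset,
Φ⁻¹((r − 3/8)/(n + 1/4)) with average ranks for ties — the standard choice in
molecular-QTL pipelines because it bounds the influence of outliers and makes
the per-feature null exactly t-distributed. Cross-sample quantile
normalization to a common reference distribution is a different operation and
is intentionally not the default.

## QTL scan

Pairs are tested within an inclusive 1 Mb window measured from the variant to
the nearest region edge. Each pair is an OLS fit of normal scores on
`[1, dosage, covariates]` with pairwise deletion of missing dosages; pairs
monomorphic after deletion are skipped and tallied rather than reported with
degenerate statistics. Only this single nominal pass is implemented: FDR is
taken over all tested pairs of a dataset with Storey's q-value, and the
permutation-based top-variant pass used by some external mappers is out of
scope. FDR is controlled per dataset (per tissue state here), not jointly
across datasets.

The Storey estimator uses the λ grid 0.05–0.95 (step 0.05), a cubic
smoothing spline (df = 3) evaluated at λ = 0.95, clipped to (0, 1]. Below
100 p-values the spline is unstable, so the estimator falls back to the
fixed-λ = 0.5 form with a warning. π₁ = 1 − π₀ doubles as the GWAS-overlap
statistic per QTL category.

## Matched controls and enrichment

Control variants are drawn without replacement, stratified by MAF bin
(width 0.05), LD-proxy-count bin ({0, 1–5, 6–20, 21–50, >50} partners at
r² > 0.2) and variant type, at a default 1:1 ratio. The bin widths and the
ratio are package defaults chosen to keep strata fillable at desk scale —
the matching scheme itself (LD, MAF, type) is the fixed part; the proxy
threshold reuses the same r² > 0.2 as the GWAS LD-block expansion and is
configurable. An underfilled stratum falls back to the nearest MAF bin with
a warning; a signal variant that still cannot be matched contributes no
control and is counted. Enrichment is a two-sided Fisher exact test per
feature with Haldane–Anscombe +0.5 correction for zero cells and Bonferroni
adjustment over the declared family size (e.g. 801 TFs, 150 RBPs — pass
`n_tests` when testing a subset of a larger family).

## Specificity and target linking

Sharing is defined at the (variant, eRNA) pair level and requires
significance in both states — the strict reading; "significant in one plus
nominal in the other" would give larger shared counts and is easy to compute
from the retained full tables. Target links combine distance (region edge to
TSS ≤ 1 Mb) with partial correlation adjusted for tumor purity, using
Benjamini–Hochberg across candidates: BH is used here (not Storey) because
target linking is a screening step over a modest candidate list, while the
QTL scan, with its much larger and null-dominated p-value pool, uses the
adaptive Storey estimator. Purity adjustment defaults to on; disable by
passing `covars = NULL`.

## Association models

Four codings of a 0/1/2 dosage: additive (0/1/2), recessive (homozygous
effect allele vs rest), allelic (2N allele expansion with duplicated
covariates), and a homozygote-vs-homozygote genotype contrast that
reproduces the common CC-vs-TT table presentation. Age enters continuous;
smoking and drinking as binary indicators. The effect allele is fixed by the
caller and never auto-flipped to the minor allele. Stage combination is
reported both as a pooled re-fit with stage indicators and as fixed-effect
inverse-variance meta-analysis; neither is privileged. Separation aborts
with an error instead of silently penalizing.

## The synthetic cohorts

The generator's defaults describe the cohort the pipeline targets: 154
expression samples (the paired-tissue design), 10 replicate peak samples per
assay, planted additive effects of β = 1 SD per allele at MAF ≥ 0.1, latent
log-RPKM noise of 1, a mean region abundance of RPKM ≈ 2, Beta(10, 1) INFO
scores, and a planted per-allele odds ratio of 0.91 in the case-control
arm. LD is a first-order haplotype-copying chain (adjacent-variant copy
probability `ld_rho`, default 0.8, in blocks of 10): simple, desk-scale, in
Hardy–Weinberg equilibrium by construction, and with tunable adjacent r² —
sufficient to exercise proxy counting and LD-block logic. It does *not*
emulate coalescent allele-frequency/LD coupling, recombination hotspots, or
population stratification. Read counts are Poisson, not negative binomial:
the analysis consumes RPKM, and planting effects on the latent log scale
makes overdispersion a second-order concern.

Because of these simplifications, passing tests demonstrate correctness of
the statistical machinery and recoverability of planted structure under the
stated model — they do not certify performance on real tissue data with
mappability artifacts, unmodeled ancestry structure, or non-Poisson counts.

## Numerical and degenerate-input behavior

Exact fits (zero residual variance) report p = 10⁻³⁰⁰ rather than 0 so that
downstream q-value machinery, which requires p ∈ (0, 1], is well defined.
Constant features transform to all-zero scores with a warning; constant
residuals make a partial correlation an error (tolerance 10⁻¹⁰ relative).
QC boundary semantics mirror the removal phrasing: MAF exactly at the 5%
threshold is kept, missing rate exactly at 5% is removed, INFO exactly 0.4
is kept. A chromosome-naming mismatch between two interval inputs (e.g.
`chr1` vs `1`) is an error listing the offending names, never a silent empty
intersection.

## The truth-recovery demonstration

`demo_config()` defines the configuration used to demonstrate end-to-end
recovery: zero peak noise, `ld_rho = 0` (so planted variants are the only
truly associated ones — with LD on, block-mates of planted variants are
genuinely associated and would rightly be called), 4 planted cis effects per
state with half shared, and 3 planted target links. Under zero peak noise
the enhancer and eRNA-region sets are recovered *exactly*. For the QTL and
link calls, exactness has an irreducible statistical limit: controlling FDR
at 5% concedes, by design, about 0.05 × (number of calls) unplanted calls in
expectation at any problem size, so the acceptance checks require every
planted effect to be recovered and allow at most ⌈0.05 × calls⌉ unplanted
extras. The |pcor| ≥ 0.3 gate makes false links additionally rare.

## Problem sizes used by the test suite

The calibration suites run at the sizes stated with them: type-I error over
50 seeds × 2,000 null fits at n = 200; Storey π₀ on m = 10,000 uniform
p-values; β-recovery coverage over 100 seeds at n = 150; odds-ratio recovery
over 100 replicates of 50,000 subjects; oracle equivalence on 10 kb toy
chromosomes with hundreds of random intervals. These sizes give Monte-Carlo
standard errors comfortably inside the asserted bands while keeping the
suite quick on a single CPU.

## Known limitations

No strand-specific or spliced-read handling; no trans-QTLs, conditional
secondary signals, or interaction QTLs; LD is consumed from a supplied table
(never computed from a reference panel); variant functional categories are
consumed, not derived from sequence; polyadenylation bias of conventional
RNA-seq against unstable eRNAs is inherited from the data, not corrected.
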