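# ernaqtl

Mapping genetic variants that regulate enhancer RNA expression in *cis*
(eRNA quantitative trait loci, eRNAQTLs), with the full analysis path needed
to go from chromatin peaks and read alignments to condition-specific QTLs,
enrichment statistics, target genes, and disease association.

Enhancers that are actively transcribing produce short non-coding RNAs
(eRNAs). Because eRNA output is a direct readout of enhancer activity,
variants that change it are strong candidates for the regulatory mechanisms
behind GWAS loci, and comparing QTLs mapped in tumor tissue against matched
normal tissue separates regulatory effects that are constitutive from those
switched on by the disease state. This package is written for statistical
geneticists and regulatory-genomics analysts who want that entire pipeline as
composable, tested R functions, exercised end-to-end on synthetic data with
planted effects so every stage can be validated against known truth.

## What it computes

**Enhancer annotation.** Replicate ATAC-seq and H3K27ac peak sets are reduced
to active enhancers by three rules: a peak base must be supported by at least
2 replicate samples (resolved per base on the merged union), accessibility
must be confirmed by H3K27ac overlap, and candidates within ±2.5 kb of any
transcription start site are discarded.

**eRNA quantification.** Each enhancer defines a ±3 kb region around its
midpoint; regions overlapping protein-coding genes (±1 kb extension) are
excluded; reads are counted per region and normalized as
RPKM = count / (length_kb · library/10⁶). Detectable eRNAs have mean
RPKM ≥ 0.5 and are expressed in more than 50% of samples (an RPM ≥ 1
consortium-style mode is also provided). For mapping, each eRNA is
rank-transformed to normal scores, Φ⁻¹((r − 3/8)/(n + 1/4)).

**Genotype QC.** Variants are dropped when INFO < 0.4, MAF < 5%, missing
rate ≥ 5%, or Hardy–Weinberg exact-test p < 10⁻⁶ (Wigginton-style exact
test, implemented here and checked against full enumeration).

**cis-QTL model.** For every variant–eRNA pair within 1 Mb,

```
y_e = α + β·g + Σ_k γ_k c_k + ε
```

where `y_e` is the normalized eRNA score, `g` the allele dosage and `c_k`
the covariates (population structure, batch, age, sex, tumor stage). The
two-sided p comes from the t distribution on β̂. Significance is controlled
per dataset by Storey's q-value: π₀ is estimated from
π₀(λ) = #{p > λ}/(m(1−λ)) with a cubic-spline smoother, and
q_(i) = min_{j≥i} π₀·m·p_(j)/j. The same estimator yields π₁ = 1 − π₀ as a
GWAS-overlap statistic per QTL category.

**Downstream.** Tumor/normal sharing is classified at the
(variant, eRNA)-pair level; matched-control enrichment draws controls
stratified by MAF bin, LD-proxy count (r² > 0.2) and variant type and tests
2×2 tables by two-sided Fisher exact test with Bonferroni correction;
target genes are linked by distance (≤ 1 Mb) plus tumor-purity-adjusted
partial correlation (|pcor| ≥ 0.3, BH FDR < 0.05); case-control association
fits additive, recessive, allelic and homozygote-contrast logistic models
per stage and combines stages by pooled re-fit or inverse-variance
meta-analysis.

**Synthetic data.** `sim_config()` / `simulate_*()` generate the whole input
universe — jittered replicate peaks, LD-structured genotypes in HWE built
from a haplotype-copying chain, eRNA counts with planted additive cis
effects and covariate structure, purity-confounded target genes, and
case-control cohorts with a planted per-allele odds ratio — together with
truth tables used by the tests.

## Worked example

```r
library(ernaqtl)
cfg <- sim_config(seed = 42)        # 154 samples, 400 variants, 10 planted QTLs per state
res <- run_pipeline(cfg)
summary(res$states$tumor$qtl)
```

```
eRNA cis-QTL scan summary
  tested pairs: 9014   significant: 53  (FDR 0.05 )
  eRNAs with >= 1 QTL: 12   pi0: 0.9651 
  strongest associations:
 variant_id    erna_id distance   n      beta         se   t_stat            p
   var00215 eRNA_00007   578006 154 0.9220114 0.09329622 9.882623 5.319783e-18
   var00074 eRNA_00012   382442 154 0.8741380 0.09220702 9.480168 5.922890e-17
   ...
```

53 pairs are significant at FDR 0.05: the 10 planted variants (true β = 1;
the top fitted β̂ ≈ 0.92 and 0.87 above) plus their LD block-mates, which are
genuinely associated through the copying-chain LD — exactly the proxy
structure real QTL scans see. Comparing states,

```r
str(res$sharing$summary)
#> $ n_tumor: 53  $ n_normal: 60  $ n_shared: 24
#> $ pct_tumor_specific : 54.7
#> $ pct_normal_specific: 60
print(res$association)
#> additive/pooled:   OR = 0.861 (95% CI 0.780-0.950), P = 0.00281  [2000 cases / 2000 controls, stage 1+2]
#> additive/ivw_meta: OR = 0.864 (95% CI 0.783-0.953), P = 0.00355  [2000 cases / 2000 controls, stage combined]
```

about half of each state's pairs are state-specific (the shared planted core
plus state-specific extras), and the two-stage case-control cohort recovers
the planted per-allele OR of 0.91 within its confidence interval. Target
linking reports the planted eRNA–gene links at |pcor| ≈ 0.99 while purity
adjustment suppresses the purity-only confounded pairs.

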