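Package: ernaqtl
Title: Enhancer RNA Quantitative Trait Locus Mapping on Matched Tumor and Normal Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping genetic variants that regulate enhancer RNA (eRNA)
    expression in cis. Covers the full analysis path: annotation of active
    enhancers from replicate ATAC-seq and H3K27ac peak sets, definition and
    RPKM quantification of eRNA-transcribing regions from read alignments,
    variant-level genotype quality control including a Hardy-Weinberg exact
    test, covariate-adjusted linear-model cis-QTL mapping with Storey q-value
    false discovery control, matched-control Fisher enrichment of QTL variants
    in genomic and regulatory features, tumor/normal specificity and pi1
    analysis, target-gene linking by distance and tumor-purity-adjusted partial
    correlation, and multi-model case-control logistic association. A
    synthetic-data module generates peak sets, LD-structured genotypes,
    expression matrices and case-control cohorts with planted effects so every
    stage can be validated against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
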