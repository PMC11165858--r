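# Variant-level genotype quality control: MAF, missingness, Hardy-Weinberg
# exact test, imputation INFO score, and the combined filter. Dosages are
# hard calls in {0, 1, 2} (expected dosages are rounded with a warning).

#' Genotype matrix container
#'
#' @param dosage integer matrix, variants x samples, values in {0, 1, 2, NA}.
#' @param variants data frame of per-variant metadata with at least
#'   `variant_id`, `chrom`, `pos`; optionally ref, alt, type, maf, info.
#' @return A list of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), nrow(dosage) == nrow(variants),
            all(c("variant_id", "chrom", "pos") %in% names(variants)))
  vals <- dosage[!is.na(dosage)]
  if (any(vals != round(vals))) {
    warning("non-integral dosages rounded to hard calls")
    dosage <- round(dosage)
  }
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE))
    stop("dosages must be in {0, 1, 2} or NA")
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- variants$variant_id
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "variants x", ncol(x$dosage),
      "samples\n")
  invisible(x)
}

#' Minor allele frequency of a dosage vector
#'
#' Alt-allele frequency over non-missing alleles, folded to <= 0.5.
#'
#' @param dosages integer vector in {0, 1, 2, NA}.
#' @return Frequency in [0, 0.5].
#' @export
compute_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("all dosages missing")
  f <- sum(d) / (2 * length(d))
  min(f, 1 - f)
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact p-value: the sum of probabilities, conditional on the
#' allele counts, of all heterozygote counts whose probability does not
#' exceed that of the observed count (the standard exact formulation used for
#' genotyping QC). Vectorized over the three count vectors.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value(s) in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  mapply(.hwe_exact1, n_AA, n_Aa, n_aa, USE.NAMES = FALSE)
}

.hwe_exact1 <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes")
  n_a <- 2 * n_aa + n_Aa
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_A, n_a)
  hets <- seq(rare %% 2, rare, by = 2)  # heterozygote counts with this parity
  # log conditional probability of each het count given allele counts
  homr <- (rare - hets) / 2
  homc <- n - hets - homr
  logp <- lfactorial(n) - lfactorial(hets) - lfactorial(homr) -
    lfactorial(homc) + hets * log(2) +
    lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Per-variant QC statistics
#'
#' Computes MAF, missing rate and Hardy-Weinberg exact p for every variant.
#' The HWE test can be restricted to a subset of samples (e.g. controls only
#' in a case-control cohort).
#'
#' @param geno a `genotype_matrix`.
#' @param hwe_samples optional character vector of sample ids for the HWE
#'   test (default: all samples).
#' @return Data frame: variant_id, maf, missing_rate, hwe_p (plus `info` if
#'   present in the variant metadata).
#' @export
genotype_qc_stats <- function(geno, hwe_samples = NULL) {
  d <- geno$dosage
  maf <- apply(d, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    f <- sum(x) / (2 * length(x)); min(f, 1 - f)
  })
  miss <- rowMeans(is.na(d))
  dh <- if (is.null(hwe_samples)) d else d[, hwe_samples, drop = FALSE]
  nAA <- rowSums(dh == 0, na.rm = TRUE)
  nAa <- rowSums(dh == 1, na.rm = TRUE)
  naa <- rowSums(dh == 2, na.rm = TRUE)
  hwe <- hwe_exact_test(nAA, nAa, naa)
  out <- data.frame(variant_id = geno$variants$variant_id, maf = maf,
                    missing_rate = miss, hwe_p = hwe,
                    stringsAsFactors = FALSE)
  if (!is.null(geno$variants$info)) out$info <- geno$variants$info
  rownames(out) <- NULL
  out
}

#' Variant quality-control filter
#'
#' Keeps variants passing all four criteria, with boundary semantics
#' mirroring the removal rules: INFO < `info_min` removed, MAF < `maf_min`
#' removed (exact boundary retained), missing rate >= `miss_max` removed
#' (exact boundary removed), HWE p < `hwe_min` removed. Variants without an
#' INFO score pass that criterion. The filter is idempotent and
#' order-independent.
#'
#' @param geno a `genotype_matrix`.
#' @param maf_min,miss_max,hwe_min,info_min thresholds (defaults 0.05, 0.05,
#'   1e-6, 0.4).
#' @param hwe_samples passed to [genotype_qc_stats()].
#' @return Filtered `genotype_matrix` with attribute `qc_tally`, a named
#'   vector counting removals per criterion (non-exclusive) plus the total.
#' @export
qc_filter <- function(geno, maf_min = 0.05, miss_max = 0.05,
                      hwe_min = 1e-6, info_min = 0.4, hwe_samples = NULL) {
  st <- genotype_qc_stats(geno, hwe_samples = hwe_samples)
  fail_maf <- !is.na(st$maf) & st$maf < maf_min
  fail_miss <- st$missing_rate >= miss_max
  fail_hwe <- !is.na(st$hwe_p) & st$hwe_p < hwe_min
  fail_info <- if (!is.null(st$info)) !is.na(st$info) & st$info < info_min
  else rep(FALSE, nrow(st))
  keep <- !(fail_maf | fail_miss | fail_hwe | fail_info) & !is.na(st$maf)
  out <- genotype_matrix(geno$dosage[keep, , drop = FALSE],
                         geno$variants[keep, , drop = FALSE])
  out$qc_stats <- st[keep, , drop = FALSE]
  structure(out, qc_tally = c(maf = sum(fail_maf), missing = sum(fail_miss),
                              hwe = sum(fail_hwe), info = sum(fail_info),
                              removed = sum(!keep)))
}

#' Read genotypes from a VCF
#'
#' Parses GT hard calls into a dosage matrix (alt-allele count; `./.` becomes
#' NA) and pulls an imputation score from a named INFO key if present.
#' Positions are converted to 0-based.
#'
#' @param path VCF file (plain text or gzipped).
#' @param info_key INFO key holding the imputation confidence score.
#' @return A `genotype_matrix`.
#' @export
read_vcf_genotypes <- function(path, info_key = "INFO_SCORE") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|.", "."), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a)
             sum(as.integer(a != "0")), integer(1)))
  }
  dosage <- matrix(alt_count(as.vector(gt)), nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = info_key)))
  ref <- fix$REF; alt <- fix$ALT
  variants <- data.frame(variant_id = fix$ID,
                         chrom = fix$CHROM,
                         pos = as.integer(fix$POS) - 1L,
                         ref = ref, alt = alt,
                         type = ifelse(nchar(ref) != nchar(alt), "indel", "SNV"),
                         stringsAsFactors = FALSE)
  if (!all(is.na(info))) variants$info <- info
  variants$maf <- apply(dosage, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    f <- sum(x) / (2 * length(x)); min(f, 1 - f)
  })
  genotype_matrix(dosage, variants)
}
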