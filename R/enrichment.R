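# Matched-control construction and 2x2 enrichment of QTL variants in genomic
# and regulatory features; GWAS LD-block enrichment and pi1-based GWAS
# overlap.

#' Count LD proxies per variant
#'
#' Number of other variants in linkage disequilibrium (`r2 > r2_min`) with
#' each query variant, from a supplied pairwise LD table.
#'
#' @param ids variant ids to annotate.
#' @param ld_table data frame with columns id_a, id_b, r2.
#' @param r2_min LD threshold (default 0.2).
#' @return Named integer vector (0 for variants absent from the table).
#' @export
ld_proxy_counts <- function(ids, ld_table, r2_min = 0.2) {
  out <- stats::setNames(integer(length(ids)), ids)
  if (!is.null(ld_table) && nrow(ld_table)) {
    keep <- ld_table$r2 > r2_min
    tab <- table(c(ld_table$id_a[keep], ld_table$id_b[keep]))
    hit <- intersect(names(tab), ids)
    out[hit] <- as.integer(tab[hit])
  }
  out
}

# Stratum label: MAF bin (width maf_bin) x LD-proxy-count bin x variant type.
variant_stratum <- function(annot, maf_bin = 0.05,
                            proxy_breaks = c(-Inf, 0, 5, 20, 50, Inf)) {
  mb <- floor(annot$maf / maf_bin)
  pb <- cut(annot$ld_proxy_count, proxy_breaks, labels = FALSE)
  paste(mb, pb, annot$variant_type, sep = "|")
}

#' Draw matched control variants
#'
#' For each signal variant, draws `ratio` controls without replacement from
#' pool variants in the same stratum: MAF bin (width `maf_bin` by default
#' 0.05), LD-proxy-count bin ({0, 1-5, 6-20, 21-50, >50} proxies), and
#' variant type. An empty stratum falls back to the nearest MAF bin (same
#' proxy bin and type) with a warning; a signal variant that still cannot be
#' matched contributes no control and is recorded in the `unmatched`
#' attribute.
#'
#' @param signal character vector of signal variant ids.
#' @param pool data frame of candidate controls: variant_id, maf,
#'   ld_proxy_count, variant_type. Must be disjoint from `signal`.
#' @param ratio controls per signal variant.
#' @param maf_bin MAF bin width.
#' @param seed optional integer seed for reproducible draws.
#' @return Character vector of control ids, attribute `unmatched` counting
#'   signal variants without a full complement of controls.
#' @export
match_controls <- function(signal, pool, ratio = 1, maf_bin = 0.05,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(signal %in% pool$variant_id))
    stop("control pool must be disjoint from the signal set")
  need <- c("variant_id", "maf", "ld_proxy_count", "variant_type")
  if (!all(need %in% names(pool)))
    stop("pool must carry columns ", paste(need, collapse = ", "))
  sig <- attr(signal, "annot")
  if (is.null(sig))
    stop("signal must carry an 'annot' attribute (see annotate_signal)")
  sig_stratum <- variant_stratum(sig, maf_bin)
  pool_stratum <- variant_stratum(pool, maf_bin)
  pool_mb <- floor(pool$maf / maf_bin)
  available <- rep(TRUE, nrow(pool))
  controls <- character(0)
  unmatched <- 0L
  warned <- FALSE
  for (st in unique(sig_stratum)) {
    n_need <- ratio * sum(sig_stratum == st)
    idx <- which(available & pool_stratum == st)
    take <- idx[sample.int(length(idx), min(length(idx), n_need))]
    short <- n_need - length(take)
    if (short > 0) {
      if (!warned) {
        warning("control stratum underfilled; falling back to nearest MAF bin")
        warned <- TRUE
      }
      parts <- strsplit(st, "|", fixed = TRUE)[[1]]
      mb0 <- as.numeric(parts[1])
      rest <- paste(parts[2], parts[3], sep = "|")
      for (off in 1:9) {
        for (mb in c(mb0 - off, mb0 + off)) {
          if (short <= 0) break
          idx2 <- which(available & pool_mb == mb &
                          paste(cut(pool$ld_proxy_count,
                                    c(-Inf, 0, 5, 20, 50, Inf), labels = FALSE),
                                pool$variant_type, sep = "|") == rest)
          idx2 <- setdiff(idx2, take)
          more <- idx2[sample.int(length(idx2), min(length(idx2), short))]
          take <- c(take, more)
          short <- short - length(more)
        }
        if (short <= 0) break
      }
      unmatched <- unmatched + max(0L, short)
    }
    available[take] <- FALSE
    controls <- c(controls, pool$variant_id[take])
  }
  structure(controls, unmatched = unmatched)
}

#' Attach matching annotation to a signal id vector
#'
#' @param ids signal variant ids.
#' @param annot data frame with variant_id, maf, ld_proxy_count,
#'   variant_type covering `ids`.
#' @return `ids` with the matching annotation (rows aligned to `ids`) stored
#'   in attribute `annot`.
#' @export
annotate_signal <- function(ids, annot) {
  rows <- match(ids, annot$variant_id)
  if (anyNA(rows)) stop("annotation missing for ",
                        sum(is.na(rows)), " signal variants")
  structure(ids, annot = annot[rows, , drop = FALSE])
}

#' Fisher enrichment of signal vs matched controls in features
#'
#' For each feature, builds the 2x2 table of in/out-of-feature by
#' signal/control and reports the two-sided Fisher exact p, the odds ratio
#' with Haldane-Anscombe +0.5 continuity correction when any cell is zero, a
#' 95% CI from the log-OR normal approximation, and the Bonferroni-adjusted
#' p (`min(1, p * n_tests)`).
#'
#' @param signal,controls disjoint character vectors of variant ids.
#' @param membership named list: feature -> character vector of member
#'   variant ids.
#' @param n_tests number of tests for the Bonferroni correction (defaults to
#'   the number of features; pass e.g. 801 when testing a subset of a larger
#'   feature family).
#' @return Data frame: feature, a, b, c, d, or_, ci_low, ci_high, p, p_adj,
#'   n_tests.
#' @export
fisher_enrichment <- function(signal, controls, membership,
                              n_tests = length(membership)) {
  if (any(signal %in% controls))
    stop("signal and control sets must be disjoint")
  rows <- lapply(names(membership), function(f) {
    mem <- membership[[f]]
    a <- sum(signal %in% mem); b <- length(signal) - a
    c_ <- sum(controls %in% mem); d <- length(controls) - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    cc <- if (any(c(a, b, c_, d) == 0)) 0.5 else 0
    or_ <- ((a + cc) * (d + cc)) / ((b + cc) * (c_ + cc))
    se <- sqrt(sum(1 / (c(a, b, c_, d) + cc)))
    data.frame(feature = f, a = a, b = b, c = c_, d = d, or_ = or_,
               ci_low = exp(log(or_) - 1.96 * se),
               ci_high = exp(log(or_) + 1.96 * se),
               p = p, p_adj = min(1, p * n_tests), n_tests = n_tests,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enrichment of QTL variants in GWAS LD blocks
#'
#' Feature membership is "is a GWAS tag SNP or in LD (r2 > `r2_min`) with
#' one"; enrichment of the QTL set vs matched controls is then a single
#' Fisher test.
#'
#' @param qtl_ids QTL variant ids (the signal).
#' @param gwas_tags GWAS tag-SNP ids.
#' @param ld_table pairwise LD table (id_a, id_b, r2).
#' @param controls matched control ids.
#' @param r2_min LD threshold (default 0.2).
#' @return One-row enrichment data frame (see [fisher_enrichment()]).
#' @export
gwas_ld_block_enrichment <- function(qtl_ids, gwas_tags, ld_table, controls,
                                     r2_min = 0.2) {
  block <- gwas_tags
  if (!is.null(ld_table) && nrow(ld_table)) {
    keep <- ld_table$r2 > r2_min
    block <- unique(c(block,
                      ld_table$id_b[keep & ld_table$id_a %in% gwas_tags],
                      ld_table$id_a[keep & ld_table$id_b %in% gwas_tags]))
  }
  fisher_enrichment(qtl_ids, controls, list(gwas_ld_block = block),
                    n_tests = 1)
}

#' pi1 enrichment for low GWAS p-values per category
#'
#' For each variant category, applies the Storey pi0 estimator to the
#' category's GWAS p-values and reports `pi1 = 1 - pi0`, the estimated
#' proportion of true associations — the standard statistic for quantifying
#' GWAS overlap of a molecular-QTL class.
#'
#' @param category_variants named list: category -> variant ids.
#' @param gwas_p named numeric vector of GWAS p-values.
#' @return Named numeric vector of pi1 per category.
#' @export
pi1_gwas_enrichment <- function(category_variants, gwas_p) {
  vapply(category_variants, function(ids) {
    p <- gwas_p[names(gwas_p) %in% ids]
    if (length(p) < 100)
      warning("fewer than 100 GWAS p-values in a category; pi1 unstable")
    1 - suppressWarnings(storey_qvalues(p)$pi0)
  }, numeric(1))
}

#' Correlate enrichment ratios with expression fold change
#'
#' Computes `log(tumor_specific_or / shared_or)` per feature and its Spearman
#' correlation with the features' expression fold changes. Features with a
#' non-positive OR are dropped with a warning.
#'
#' @param tumor_specific_or,shared_or named numeric vectors of odds ratios.
#' @param feature_fc named numeric vector of fold changes.
#' @return List with rho, p, n.
#' @export
enrichment_ratio_vs_expression <- function(tumor_specific_or, shared_or,
                                           feature_fc) {
  feats <- Reduce(intersect, list(names(tumor_specific_or), names(shared_or),
                                  names(feature_fc)))
  ts <- tumor_specific_or[feats]; sh <- shared_or[feats]
  bad <- ts <= 0 | sh <= 0
  if (any(bad)) {
    warning(sum(bad), " feature(s) with non-positive OR dropped")
    feats <- feats[!bad]; ts <- ts[!bad]; sh <- sh[!bad]
  }
  ratio <- log(ts / sh)
  ct <- suppressWarnings(
    stats::cor.test(ratio, feature_fc[feats], method = "spearman",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(feats))
}
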