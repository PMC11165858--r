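# Tumor/normal QTL sharing, effect concordance, expression-pattern classes,
# and target-gene linking via distance plus purity-adjusted partial
# correlation.

pair_key <- function(x) paste(x$variant_id, x$erna_id, sep = "\r")

#' Classify QTL sharing between tumor and normal states
#'
#' Sharing is defined at the pair level: a (variant, eRNA) pair is shared iff
#' it is significant in both states; otherwise it is specific to the state it
#' was found in. Summary percentages are rounded to one decimal, with
#' tissue-specific percentages taken over each state's own set.
#'
#' @param tumor,normal data frames of significant pairs with variant_id,
#'   erna_id and optionally beta (e.g. the significant subset of an
#'   `ernaqtl_set`).
#' @return List with `calls` (pair-level data frame: variant_id, erna_id,
#'   class, beta_tumor, beta_normal) and `summary` (counts and percentages).
#' @export
classify_qtl_sharing <- function(tumor, normal) {
  kt <- pair_key(tumor); kn <- pair_key(normal)
  all_keys <- union(kt, kn)
  in_t <- all_keys %in% kt; in_n <- all_keys %in% kn
  class <- ifelse(in_t & in_n, "shared",
                  ifelse(in_t, "tumor_specific", "normal_specific"))
  bt <- if (!is.null(tumor$beta)) tumor$beta[match(all_keys, kt)] else NA_real_
  bn <- if (!is.null(normal$beta)) normal$beta[match(all_keys, kn)] else NA_real_
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  calls <- data.frame(variant_id = parts[, 1], erna_id = parts[, 2],
                      class = class, beta_tumor = bt, beta_normal = bn,
                      stringsAsFactors = FALSE)
  n_t <- length(kt); n_n <- length(kn); n_sh <- sum(class == "shared")
  summary <- list(
    n_tumor = n_t, n_normal = n_n, n_shared = n_sh,
    n_tumor_specific = n_t - n_sh, n_normal_specific = n_n - n_sh,
    pct_tumor_specific = round(100 * (n_t - n_sh) / n_t, 1),
    pct_normal_specific = round(100 * (n_n - n_sh) / n_n, 1))
  list(calls = calls, summary = summary)
}

#' Effect-size concordance of shared QTLs
#'
#' Fraction of shared pairs whose effects have the same sign in both states
#' (a zero effect counts as concordant with either sign, flagged), plus the
#' Pearson correlation of the two effect sizes.
#'
#' @param calls pair-level calls from [classify_qtl_sharing()].
#' @return List with concordance, r, n, n_zero_beta.
#' @export
effect_concordance <- function(calls) {
  sh <- calls[calls$class == "shared" &
                !is.na(calls$beta_tumor) & !is.na(calls$beta_normal), ,
              drop = FALSE]
  if (nrow(sh) < 2) stop("need at least 2 shared pairs with both effects")
  zero <- sh$beta_tumor == 0 | sh$beta_normal == 0
  conc <- sign(sh$beta_tumor) == sign(sh$beta_normal) | zero
  list(concordance = mean(conc),
       r = stats::cor(sh$beta_tumor, sh$beta_normal),
       n = nrow(sh), n_zero_beta = sum(zero))
}

#' Classify eRNA expression patterns across cancer types
#'
#' Classes by number of cancer types in which an eRNA is detectable:
#' specific (exactly 1), intermediate (2-9), ubiquitous (>= 10). eRNAs
#' detected in no type are excluded from the denominator and reported
#' separately. Percentages are rounded to two decimals.
#'
#' @param detectability logical matrix, eRNAs x cancer types (TRUE =
#'   detectable in that type, e.g. from per-type [detectability_filter()]
#'   runs).
#' @return List with `patterns` (erna_id, n_types_detected, class) and
#'   `summary` (counts, percentages, n_undetected).
#' @export
classify_expression_pattern <- function(detectability) {
  n_types <- rowSums(detectability)
  detected <- n_types >= 1
  nt <- n_types[detected]
  class <- ifelse(nt == 1, "specific",
                  ifelse(nt <= 9, "intermediate", "ubiquitous"))
  patterns <- data.frame(
    erna_id = if (!is.null(rownames(detectability)))
      rownames(detectability)[detected] else which(detected),
    n_types_detected = nt, class = class, stringsAsFactors = FALSE)
  n <- sum(detected)
  cnt <- c(specific = sum(class == "specific"),
           intermediate = sum(class == "intermediate"),
           ubiquitous = sum(class == "ubiquitous"))
  summary <- list(n = n, counts = cnt,
                  percentages = round(100 * cnt / n, 2),
                  n_undetected = sum(!detected))
  list(patterns = patterns, summary = summary)
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation of the residuals of `x` and `y` after OLS on
#' `[1, covars]`; two-sided p from the t distribution with `n - k - 2`
#' degrees of freedom. With no covariates this reduces to the plain Pearson
#' correlation.
#'
#' @param x,y numeric vectors.
#' @param covars optional numeric matrix/data frame of covariates.
#' @return List with estimate, p, n.
#' @export
partial_correlation <- function(x, y, covars = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covars) || NCOL(covars) == 0) {
    rx <- x; ry <- y; k <- 0L
  } else {
    C <- cbind(1, as.matrix(covars))
    k <- ncol(C) - 1L
    if (n <= k + 2) stop("need n > number of covariates + 2")
    rx <- stats::lm.fit(C, x)$residuals
    ry <- stats::lm.fit(C, y)$residuals
  }
  if (stats::sd(rx) <= 1e-10 * (stats::sd(x) + 1e-300) ||
      stats::sd(ry) <= 1e-10 * (stats::sd(y) + 1e-300))
    stop("constant residuals: partial correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - k - 2L
  t_stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(estimate = r, p = 2 * stats::pt(-abs(t_stat), df), n = n)
}

#' Link eRNAs to target genes
#'
#' Candidate pairs are (eRNA region, gene) with distance from the region
#' edge to the gene TSS at most `window` bp. Each candidate gets a
#' purity-adjusted (or generally covariate-adjusted) partial correlation
#' between eRNA and gene expression; q-values are Benjamini-Hochberg over
#' all candidates. A link is reported iff `|pcor| >= pcor_min` and
#' `q < fdr`.
#'
#' @param erna_expr,gene_expr expression matrices sharing sample columns.
#' @param regions eRNA region data frame.
#' @param genes gene models with tss.
#' @param covars optional covariates (e.g. tumor purity), samples x k.
#' @param window distance threshold in bp (default 1e6).
#' @param pcor_min partial-correlation magnitude threshold (default 0.3).
#' @param fdr BH FDR threshold (default 0.05).
#' @return List with `links` (passing pairs) and `candidates` (all tested
#'   pairs: erna_id, gene_id, distance, pcor, p, q).
#' @export
link_targets <- function(erna_expr, gene_expr, regions, genes, covars = NULL,
                         window = 1e6, pcor_min = 0.3, fdr = 0.05) {
  common <- intersect(colnames(erna_expr), colnames(gene_expr))
  if (length(common) < 4) stop("fewer than 4 shared samples")
  erna_expr <- erna_expr[, common, drop = FALSE]
  gene_expr <- gene_expr[, common, drop = FALSE]
  C <- if (is.null(covars)) NULL else as.matrix(covars)[common, , drop = FALSE]
  regions <- regions[regions$erna_id %in% rownames(erna_expr), , drop = FALSE]
  genes <- genes[genes$gene_id %in% rownames(gene_expr), , drop = FALSE]
  cand <- lapply(seq_len(nrow(regions)), function(i) {
    g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    d <- pmax(0, regions$start[i] - g$tss, g$tss - (regions$end[i] - 1L))
    ok <- d <= window
    if (!any(ok)) return(NULL)
    data.frame(erna_id = regions$erna_id[i], gene_id = g$gene_id[ok],
               distance = d[ok], stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0)
    return(list(links = NULL,
                candidates = data.frame(erna_id = character(0),
                                        gene_id = character(0))))
  pc <- vapply(seq_len(nrow(cand)), function(i) {
    r <- partial_correlation(erna_expr[cand$erna_id[i], ],
                             gene_expr[cand$gene_id[i], ], C)
    c(r$estimate, r$p)
  }, numeric(2))
  cand$pcor <- pc[1, ]
  cand$p <- pc[2, ]
  cand$q <- stats::p.adjust(cand$p, method = "BH")
  rownames(cand) <- NULL
  list(links = cand[abs(cand$pcor) >= pcor_min & cand$q < fdr, , drop = FALSE],
       candidates = cand)
}

#' Correlate eRNA expression with cell-type fractions
#'
#' Purity-adjusted partial correlation for every (eRNA, cell type) pair,
#' with BH FDR across the whole table. The fraction matrix is consumed as
#' supplied (deconvolution is upstream of this package).
#'
#' @param erna_expr expression matrix (eRNAs x samples).
#' @param fractions cell-type fraction matrix (samples x cell types).
#' @param purity numeric vector of tumor purity per sample.
#' @param fdr BH threshold used for the `significant` flag.
#' @return Data frame: erna_id, cell_type, pcor, p, q, significant.
#' @export
correlate_with_fractions <- function(erna_expr, fractions, purity,
                                     fdr = 0.05) {
  fractions <- as.matrix(fractions)
  stopifnot(ncol(erna_expr) == nrow(fractions),
            length(purity) == nrow(fractions))
  grid <- expand.grid(erna_id = rownames(erna_expr),
                      cell_type = colnames(fractions),
                      stringsAsFactors = FALSE)
  pc <- vapply(seq_len(nrow(grid)), function(i) {
    r <- partial_correlation(erna_expr[grid$erna_id[i], ],
                             fractions[, grid$cell_type[i]],
                             covars = purity)
    c(r$estimate, r$p)
  }, numeric(2))
  grid$pcor <- pc[1, ]
  grid$p <- pc[2, ]
  grid$q <- stats::p.adjust(grid$p, method = "BH")
  grid$significant <- grid$q < fdr
  grid
}
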