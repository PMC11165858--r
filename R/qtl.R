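# cis-QTL mapping: candidate pair enumeration within a window, per-pair
# covariate-adjusted ordinary least squares on normalized expression, and
# Storey q-value false discovery control over all tested pairs.

#' Enumerate cis variant-region pairs
#'
#' A variant pairs with a region if its distance to the region is at most
#' `window` bp (0 inside the region, otherwise distance to the nearest
#' region edge; a variant at exactly `window` bp is paired).
#'
#' @param variants per-variant metadata with chrom and pos (0-based).
#' @param regions eRNA region data frame.
#' @param window cis window in bp (default 1e6).
#' @return Data frame: variant_id, erna_id, distance.
#' @export
cis_pairs <- function(variants, regions, window = 1e6) {
  out <- lapply(seq_len(nrow(regions)), function(i) {
    v <- variants[variants$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(v) == 0) return(NULL)
    d <- pmax(0, regions$start[i] - v$pos, v$pos - (regions$end[i] - 1L))
    ok <- d <= window
    if (!any(ok)) return(NULL)
    data.frame(variant_id = v$variant_id[ok], erna_id = regions$erna_id[i],
               distance = d[ok], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(variant_id = character(0), erna_id = character(0),
                      distance = numeric(0))
  rownames(out) <- NULL
  out
}

#' Fit one covariate-adjusted linear QTL model
#'
#' Ordinary least squares of `y` on `[1, dosage, covariates]` with pairwise
#' deletion of missing dosages; two-sided p from the t distribution on the
#' dosage coefficient with `n - k - 2` degrees of freedom (k covariates).
#'
#' @param y normalized expression vector.
#' @param dosage alt-allele dosage vector (may contain NA).
#' @param covariates optional numeric matrix/data frame, samples x k.
#' @return List with beta, se, t_stat, p, n, df — or, when the model cannot
#'   be fit, a list with a `skip` reason (`"monomorphic-in-analysis"` or
#'   `"insufficient-samples"`).
#' @export
fit_linear_qtl <- function(y, dosage, covariates = NULL) {
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  ok <- !is.na(y) & !is.na(dosage)
  if (!is.null(C)) ok <- ok & stats::complete.cases(C)
  n <- sum(ok)
  k <- if (is.null(C)) 0L else ncol(C)
  if (n < k + 3L) return(list(skip = "insufficient-samples"))
  d <- dosage[ok]
  if (stats::var(d) == 0) return(list(skip = "monomorphic-in-analysis"))
  X <- cbind(1, d, if (!is.null(C)) C[ok, , drop = FALSE])
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) return(list(skip = "collinear-design"))
  yy <- y[ok]
  coefs <- qr.coef(qr_x, yy)
  res <- yy - X %*% coefs
  df <- n - ncol(X)
  rss <- sum(res^2)
  xtxinv <- chol2inv(qr.R(qr_x))
  se <- sqrt(max(rss / df, 0) * xtxinv[2, 2])
  beta <- coefs[2]
  if (se == 0) {
    t_stat <- sign(beta) * Inf
    p <- 1e-300
  } else {
    t_stat <- beta / se
    p <- max(2 * stats::pt(-abs(t_stat), df), 1e-300)
  }
  list(beta = unname(beta), se = se, t_stat = unname(t_stat), p = unname(p),
       n = n, df = df)
}

#' Storey q-values and pi0 estimate
#'
#' Estimates the proportion of true nulls pi0 from the p-value distribution:
#' `pi0(lambda) = #{p > lambda} / (m (1 - lambda))` on a lambda grid, smoothed
#' with a cubic spline and evaluated at the largest lambda, clipped to (0, 1].
#' Q-values are the step-up `min_{j >= i} pi0 m p_(j) / j` on the sorted
#' p-values: monotone in p and invariant to input order. With fewer than 100
#' p-values the spline is unstable and a fixed lambda of 0.5 is used, with a
#' warning.
#'
#' @param p p-values in (0, 1].
#' @param lambda_grid grid for the pi0 estimate.
#' @return List of class `qvalue_result`: pi0, pi1 (= 1 - pi0), lambda, and q
#'   in the input order.
#' @export
storey_qvalues <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (m < 100) {
    warning("fewer than 100 p-values: pi0 estimated at fixed lambda = 0.5")
    pi0 <- mean(p > 0.5) / 0.5
    lambda_used <- 0.5
  } else {
    pi0_l <- vapply(lambda_grid, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda_grid, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda_grid))$y
    lambda_used <- lambda_grid
  }
  pi0 <- min(1, max(pi0, 1e-8))
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(q_sorted))))
  q <- numeric(m)
  q[o] <- q_sorted
  structure(list(pi0 = pi0, pi1 = 1 - pi0, lambda = lambda_used, q = q),
            class = "qvalue_result")
}

#' @export
print.qvalue_result <- function(x, ...) {
  cat("Storey q-values: m =", length(x$q), " pi0 =", signif(x$pi0, 4),
      " pi1 =", signif(x$pi1, 4), "\n")
  invisible(x)
}

#' Map cis eRNA QTLs
#'
#' Runs the full mapping for one dataset: cis pair enumeration, per-pair
#' covariate-adjusted OLS, then Storey q-values over all tested pairs.
#' Records with `q < fdr` are flagged significant; the full table is
#' retained. FDR is controlled per dataset (e.g. per tissue state).
#'
#' @param expr normalized expression matrix (features x samples), rownames
#'   matching `regions$erna_id`, colnames matching genotype samples.
#' @param geno a `genotype_matrix` (QC'd).
#' @param regions eRNA region data frame.
#' @param covariates optional samples x k numeric matrix/data frame
#'   (population-structure components, batch, age, sex, tumor stage...).
#' @param window cis window in bp.
#' @param fdr significance threshold on the q-value.
#' @param state optional label ("tumor"/"normal") stored on the result.
#' @return Data frame of class `ernaqtl_set` with columns variant_id,
#'   erna_id, distance, n, beta, se, t_stat, p, q, significant; attributes
#'   pi0, fdr, state, skipped (tally of untestable pairs by reason).
#' @export
map_ernaqtl <- function(expr, geno, regions, covariates = NULL,
                        window = 1e6, fdr = 0.05, state = NA_character_) {
  common <- intersect(colnames(expr), colnames(geno$dosage))
  if (length(common) < 3) stop("fewer than 3 shared samples")
  expr <- expr[, common, drop = FALSE]
  dos <- geno$dosage[, common, drop = FALSE]
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)[common, , drop = FALSE]
  regions <- regions[regions$erna_id %in% rownames(expr), , drop = FALSE]
  pairs <- cis_pairs(geno$variants, regions, window)
  fits <- vector("list", nrow(pairs))
  skipped <- character(0)
  for (i in seq_len(nrow(pairs))) {
    f <- fit_linear_qtl(expr[pairs$erna_id[i], ], dos[pairs$variant_id[i], ], C)
    if (!is.null(f$skip)) {
      skipped <- c(skipped, f$skip)
      fits[[i]] <- NULL
    } else fits[[i]] <- f
  }
  tested <- !vapply(fits, is.null, logical(1))
  out <- pairs[tested, , drop = FALSE]
  if (nrow(out)) {
    ft <- fits[tested]
    out$n <- vapply(ft, `[[`, 0, "n")
    out$beta <- vapply(ft, `[[`, 0, "beta")
    out$se <- vapply(ft, `[[`, 0, "se")
    out$t_stat <- vapply(ft, `[[`, 0, "t_stat")
    out$p <- vapply(ft, `[[`, 0, "p")
    qv <- suppressWarnings(storey_qvalues(out$p))
    out$q <- qv$q
    out$significant <- out$q < fdr
    pi0 <- qv$pi0
  } else pi0 <- NA_real_
  rownames(out) <- NULL
  structure(out, class = c("ernaqtl_set", "data.frame"),
            pi0 = pi0, fdr = fdr, state = state,
            skipped = table(skipped))
}

#' @export
print.ernaqtl_set <- function(x, ...) {
  cat("eRNA cis-QTL scan", if (!is.na(attr(x, "state")))
    paste0("(", attr(x, "state"), " state)"), "\n")
  cat("  tested pairs:     ", nrow(x), "\n")
  cat("  significant (q < ", attr(x, "fdr"), "): ",
      sum(x$significant), "\n", sep = "")
  cat("  estimated pi0:    ", signif(attr(x, "pi0"), 4), "\n")
  invisible(x)
}

#' @export
summary.ernaqtl_set <- function(object, ...) {
  sig <- object[object$significant, , drop = FALSE]
  out <- list(n_tested = nrow(object),
              n_significant = nrow(sig),
              n_ernas_with_qtl = length(unique(sig$erna_id)),
              pi0 = attr(object, "pi0"),
              fdr = attr(object, "fdr"),
              state = attr(object, "state"),
              top = utils::head(as.data.frame(object)[order(object$p), ], 5))
  class(out) <- "summary.ernaqtl_set"
  out
}

#' @export
print.summary.ernaqtl_set <- function(x, ...) {
  cat("eRNA cis-QTL scan summary\n")
  cat("  tested pairs:", x$n_tested, "  significant:", x$n_significant,
      " (FDR", x$fdr, ")\n")
  cat("  eRNAs with >= 1 QTL:", x$n_ernas_with_qtl, "  pi0:",
      signif(x$pi0, 4), "\n")
  cat("  strongest associations:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}
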