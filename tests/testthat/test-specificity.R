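# Tumor/normal sharing, effect concordance, expression patterns, partial
# correlation, target linking.

mk_pairs <- function(keys, beta = NULL) {
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  d <- data.frame(variant_id = parts[, 1], erna_id = parts[, 2],
                  stringsAsFactors = FALSE)
  if (!is.null(beta)) d$beta <- beta
  d
}

test_that("sharing classification satisfies its counting identities", {
  tum <- mk_pairs(c("v1:e1", "v2:e1", "v3:e2"))
  nor <- mk_pairs(c("v1:e1", "v4:e3"))
  out <- classify_qtl_sharing(tum, nor)
  s <- out$summary
  expect_equal(s$n_tumor_specific + s$n_shared, s$n_tumor)
  expect_equal(s$n_normal_specific + s$n_shared, s$n_normal)
  expect_equal(nrow(out$calls), length(union(c("v1:e1", "v2:e1", "v3:e2"),
                                             c("v1:e1", "v4:e3"))))
  # pair-level identity: same variant with a different eRNA is not shared
  tum2 <- mk_pairs("v1:e1"); nor2 <- mk_pairs("v1:e2")
  expect_equal(classify_qtl_sharing(tum2, nor2)$summary$n_shared, 0L)

  # disjoint -> 100%/100% specific; identical -> 0%/0%
  d1 <- mk_pairs(c("a:x", "b:y")); d2 <- mk_pairs(c("c:z", "d:w"))
  sd <- classify_qtl_sharing(d1, d2)$summary
  expect_equal(sd$pct_tumor_specific, 100)
  expect_equal(sd$pct_normal_specific, 100)
  si <- classify_qtl_sharing(d1, d1)$summary
  expect_equal(si$pct_tumor_specific, 0)
  expect_equal(si$n_shared, 2L)
})

test_that("the printed-count worked example reproduces the published percentages", {
  shared <- sprintf("s%05d:e", 1:11095)
  tum <- mk_pairs(c(shared, sprintf("t%05d:e", 1:(25983 - 11095))))
  nor <- mk_pairs(c(shared, sprintf("n%05d:e", 1:(34737 - 11095))))
  s <- classify_qtl_sharing(tum, nor)$summary
  expect_equal(s$n_shared, 11095L)
  expect_equal(s$pct_tumor_specific, 57.3)
  expect_equal(s$pct_normal_specific, 68.1)
})

test_that("effect concordance handles equal, negated, and noisy shared effects", {
  b <- c(0.5, -1, 2, 0.8)
  calls <- data.frame(variant_id = letters[1:4], erna_id = letters[1:4],
                      class = "shared", beta_tumor = b, beta_normal = b)
  ec <- effect_concordance(calls)
  expect_equal(ec$concordance, 1)
  expect_equal(ec$r, 1)
  calls$beta_normal <- -b
  ec2 <- effect_concordance(calls)
  expect_equal(ec2$concordance, 0)
  expect_equal(ec2$r, -1)

  set.seed(173)
  conc <- replicate(20, {
    bt <- rep(0.8, 50)
    calls <- data.frame(variant_id = as.character(1:50),
                        erna_id = as.character(1:50), class = "shared",
                        beta_tumor = bt + rnorm(50, 0, 0.1),
                        beta_normal = bt + rnorm(50, 0, 0.1))
    effect_concordance(calls)$concordance
  })
  expect_gt(mean(conc), 0.95)

  expect_error(effect_concordance(calls[0, ]), "at least 2")
})

test_that("expression-pattern classes follow the 1 / 2-9 / >=10 cut points", {
  det <- rbind(matrix(c(rep(TRUE, 1), rep(FALSE, 29)), 1, 30),
               matrix(c(rep(TRUE, 9), rep(FALSE, 21)), 1, 30),
               matrix(c(rep(TRUE, 10), rep(FALSE, 20)), 1, 30),
               matrix(FALSE, 1, 30))
  rownames(det) <- c("one", "nine", "ten", "none")
  out <- classify_expression_pattern(det)
  expect_equal(out$patterns$class, c("specific", "intermediate", "ubiquitous"))
  expect_equal(out$summary$n_undetected, 1L)
  expect_equal(sum(out$summary$counts), out$summary$n)

  # all eRNAs in exactly one type
  det1 <- diag(TRUE, 5)
  expect_equal(unname(classify_expression_pattern(det1)$summary
                      $percentages["specific"]), 100)
})

test_that("the printed eRNA split reproduces the published percentages", {
  n_types <- c(rep(1, 982), sample(2:9, 1117, replace = TRUE),
               sample(10:30, 297, replace = TRUE))
  det <- t(vapply(n_types, function(k) seq_len(30) <= k, logical(30)))
  out <- classify_expression_pattern(det)
  expect_equal(out$summary$n, 2396L)
  expect_equal(unname(out$summary$percentages),
               c(40.98, 46.62, 12.40))
  expect_equal(sum(out$summary$percentages), 100, tolerance = 0.01)
})

test_that("partial correlation matches the precision-matrix oracle and removes confounders", {
  set.seed(179)
  for (i in 1:10) {
    n <- 20
    C <- matrix(rnorm(n * 2), n)
    x <- rnorm(n) + C %*% c(1, -1)
    y <- rnorm(n) + C %*% c(0.5, 2)
    got <- partial_correlation(x, y, C)
    expect_equal(got$estimate, oracle_pcor(x, y, C), tolerance = 1e-10)
  }
  # no covariates: plain Pearson, same p as cor.test
  x <- rnorm(30); y <- rnorm(30)
  got <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(got$estimate, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-10)
  # y equal to the covariate: partial correlation collapses
  cv <- rnorm(40); x2 <- 2 * cv + rnorm(40, 0, 0.2)
  expect_error(partial_correlation(x2, cv, cbind(cv)), "constant residuals")
  y2 <- cv + rnorm(40, 0, 1e-8)
  expect_lt(abs(partial_correlation(x2, y2, cbind(cv))$estimate), 0.5)
})

test_that("target linking recovers planted links and rejects purity-only pairs", {
  cfg <- sim_config(seed = 181, n_genes = 10, n_enhancers = 12,
                    chrom_length = 3e6L, n_variants = 60, n_samples = 154,
                    n_links = 4, link_gamma = 1, purity_effect = 3,
                    erna_purity_effect = 1.5, noise_sd = 0.3)
  gen <- simulate_genome(cfg)
  geno <- simulate_genotypes(cfg)
  reg <- filter_coding_overlap(
    build_erna_regions(gen$enhancers, chrom_length = cfg$chrom_length),
    gen$genes)
  ex <- simulate_expression(geno, reg, gen$genes, cfg)
  purity <- setNames(ex$covariates$purity, rownames(ex$covariates))
  out <- link_targets(ex$rpkm, ex$gene_expr, reg, gen$genes,
                      covars = purity, window = cfg$window)
  got_keys <- paste(out$links$erna_id, out$links$gene_id)
  want_keys <- paste(ex$link_table$erna_id, ex$link_table$gene_id)
  expect_true(all(want_keys %in% got_keys))

  # purity adjustment removes the purity-only spurious links that plain
  # correlation accepts at the same thresholds
  plain <- link_targets(ex$rpkm, ex$gene_expr, reg, gen$genes,
                        covars = NULL, window = cfg$window)
  spurious_plain <- setdiff(paste(plain$links$erna_id, plain$links$gene_id),
                            want_keys)
  spurious_adj <- setdiff(got_keys, want_keys)
  expect_gt(length(spurious_plain), 0)
  expect_lte(length(spurious_adj), 0.1 * length(spurious_plain))

  # window = 0: only genes whose TSS lies inside a region are candidates
  w0 <- link_targets(ex$rpkm, ex$gene_expr, reg, gen$genes, covars = purity,
                     window = 0)
  expect_true(all(w0$candidates$distance == 0))
  # pcor_min = 1 keeps only exact affine relationships
  p1 <- link_targets(ex$rpkm, ex$gene_expr, reg, gen$genes, covars = purity,
                     window = cfg$window, pcor_min = 1)
  expect_equal(nrow(p1$links), 0L)
})

test_that("cell-fraction correlations respect purity adjustment", {
  set.seed(191)
  n <- 120
  purity <- rbeta(n, 5, 2)
  erna <- rbind(drv = 2 * purity + rnorm(n, 0, 0.1),
                ind = rnorm(n))
  colnames(erna) <- sprintf("S%03d", 1:n)
  fr <- cbind(ctA = 0.5 * purity + rnorm(n, 0, 0.05),  # purity-driven
              ctB = plogis(erna["ind", ] + rnorm(n, 0, 0.3)),
              ctC = runif(n))
  rownames(fr) <- colnames(erna)
  out <- correlate_with_fractions(erna, fr, purity)
  # purity-driven eRNA vs purity-driven fraction: small after adjustment
  expect_lt(abs(out$pcor[out$erna_id == "drv" & out$cell_type == "ctA"]), 0.3)
  # genuine association survives adjustment
  expect_gt(out$pcor[out$erna_id == "ind" & out$cell_type == "ctB"], 0.5)
  # independent fraction: not significant
  expect_false(out$significant[out$erna_id == "ind" & out$cell_type == "ctC"])
})
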