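# Matched controls, Fisher enrichment, GWAS LD blocks, pi1, and the
# enrichment-ratio correlation.

make_pool <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(variant_id = sprintf("p%05d", seq_len(n)),
             maf = runif(n, 0.05, 0.5),
             ld_proxy_count = sample(c(0, 1, 3, 10, 30, 80), n, replace = TRUE),
             variant_type = sample(c("SNV", "indel"), n, replace = TRUE,
                                   prob = c(0.9, 0.1)),
             stringsAsFactors = FALSE)
}

test_that("matched controls reproduce the signal stratum distribution exactly", {
  pool <- make_pool(8000)
  set.seed(139)
  sig_rows <- sample(nrow(pool), 100)
  sig_annot <- pool[sig_rows, ]
  sig_annot$variant_id <- sprintf("s%03d", seq_len(100))  # disjoint ids
  signal <- annotate_signal(sig_annot$variant_id, sig_annot)
  ctrl <- match_controls(signal, pool, ratio = 1, seed = 139)
  expect_equal(length(ctrl), 100L)
  expect_equal(attr(ctrl, "unmatched"), 0L)
  stratum <- function(a) paste(floor(a$maf / 0.05),
                               cut(a$ld_proxy_count, c(-Inf, 0, 5, 20, 50, Inf)),
                               a$variant_type)
  sig_tab <- table(stratum(sig_annot))
  ctrl_tab <- table(stratum(pool[match(ctrl, pool$variant_id), ]))
  expect_equal(as.vector(ctrl_tab[names(sig_tab)]), as.vector(sig_tab))

  # ratio 2 doubles the control count, still stratum-matched
  ctrl2 <- match_controls(signal, pool, ratio = 2, seed = 139)
  expect_equal(length(ctrl2), 200L)
  ctrl2_tab <- table(stratum(pool[match(ctrl2, pool$variant_id), ]))
  expect_equal(as.vector(ctrl2_tab[names(sig_tab)]), 2 * as.vector(sig_tab))
  expect_false(any(duplicated(ctrl2)))

  # deterministic under seed
  expect_identical(as.vector(match_controls(signal, pool, seed = 7)),
                   as.vector(match_controls(signal, pool, seed = 7)))

  # an empty stratum falls back to the nearest MAF bin with a warning
  pool_small <- pool[pool$maf > 0.2, ]
  sig2_annot <- data.frame(variant_id = "sX", maf = 0.07, ld_proxy_count = 0,
                           variant_type = "SNV")
  sig2 <- annotate_signal("sX", sig2_annot)
  expect_warning(ctrlf <- match_controls(sig2, pool_small, seed = 1),
                 "nearest MAF bin")
  expect_equal(length(ctrlf), 1L)

  expect_error(match_controls(annotate_signal(pool$variant_id[1],
                                              pool[1, ]), pool),
               "disjoint")
})

test_that("Fisher enrichment matches the worked 2x2 and the hypergeometric oracle", {
  signal <- sprintf("s%03d", 1:100)
  controls <- sprintf("c%03d", 1:100)
  mem <- list(feat = c(signal[1:30], controls[1:10]))
  r <- fisher_enrichment(signal, controls, mem)
  expect_equal(r$a, 30); expect_equal(r$c, 10)
  expect_equal(r$or_, (30 * 90) / (70 * 10), tolerance = 1e-12)
  expect_equal(r$p, oracle_fisher(30, 70, 10, 90), tolerance = 1e-9)

  set.seed(149)
  for (i in 1:20) {
    n1 <- sample(20:100, 1); n2 <- sample(20:100, 1)
    s <- sprintf("s%d", 1:n1); c_ <- sprintf("c%d", 1:n2)
    mem <- list(f = c(sample(s, sample(0:n1, 1)), sample(c_, sample(0:n2, 1))))
    r <- fisher_enrichment(s, c_, mem)
    expect_equal(r$p, oracle_fisher(r$a, r$b, r$c, r$d), tolerance = 1e-9)
  }

  # empty feature: continuity-corrected OR, p = 1
  r0 <- fisher_enrichment(signal, controls, list(empty = character(0)))
  expect_equal(r0$p, 1)
  expect_equal(r0$or_, (0.5 * 100.5) / (100.5 * 0.5))

  # Bonferroni: p_adj >= p, capped at 1
  r801 <- fisher_enrichment(signal, controls,
                            list(f = c(signal[1:3], controls[1:2])),
                            n_tests = 801)
  expect_gte(r801$p_adj, r801$p)
  expect_lte(r801$p_adj, 1)

  expect_error(fisher_enrichment(signal, signal, mem), "disjoint")
})

test_that("identically drawn signal and controls show no enrichment", {
  set.seed(151)
  nulls <- replicate(40, {
    ids <- sprintf("v%04d", sample(9999, 400))
    sig <- ids[1:200]; ctl <- ids[201:400]
    mem <- list(f = sample(ids, 120))
    r <- fisher_enrichment(sig, ctl, mem, n_tests = 10)
    c(r$or_, r$p_adj)
  })
  expect_lt(abs(mean(log(nulls[1, ]))), 0.15)
  expect_lte(mean(nulls[2, ] < 0.05), 0.05)
})

test_that("GWAS LD-block membership expands tags by r2 > threshold", {
  tags <- c("t1", "t2")
  ld <- data.frame(id_a = c("t1", "t1", "x1", "t2"),
                   id_b = c("a", "b", "t2", "c"),
                   r2 = c(0.5, 0.1, 0.9, 0.25))
  ctl <- sprintf("c%d", 1:50)
  qtl <- c("a", "x1", "b", sprintf("q%d", 1:47))
  r <- gwas_ld_block_enrichment(qtl, tags, ld, ctl, r2_min = 0.2)
  # block = {t1, t2, a (0.5), x1 (0.9), c (0.25)}; b excluded at 0.1
  expect_equal(r$a, 2)  # "a" and "x1" from the QTL set

  # r2 = 0 everywhere: membership reduces to the tags
  ld0 <- transform(ld, r2 = 0)
  r0 <- gwas_ld_block_enrichment(c("t1", qtl), tags, ld0, ctl)
  expect_equal(r0$a, 1)

  # planted co-localization: QTLs preferentially inside blocks
  set.seed(157)
  block <- sprintf("b%03d", 1:150)
  outside <- sprintf("o%03d", 1:850)
  qtl2 <- c(sample(block[1:75], 60), sample(outside[1:425], 40))
  ctl2 <- c(sample(block[76:150], 15), sample(outside[426:850], 85))
  ld2 <- data.frame(id_a = "tag", id_b = block, r2 = 0.5)
  r2 <- gwas_ld_block_enrichment(qtl2, "tag", ld2, ctl2)
  expect_gt(r2$or_, 1)
  expect_lt(r2$p, 0.01)
})

test_that("pi1 recovers planted GWAS-overlap fractions", {
  set.seed(163)
  gwas_p <- c(setNames(runif(5000), sprintf("n%04d", 1:5000)),
              setNames(c(runif(1250, 0, 1e-8), runif(3750)),
                       sprintf("m%04d", 1:5000)),
              setNames(rep(1, 200), sprintf("one%03d", 1:200)))
  cats <- list(null = sprintf("n%04d", 1:5000),
               mix25 = sprintf("m%04d", 1:5000),
               all_one = sprintf("one%03d", 1:200))
  pi1 <- suppressWarnings(pi1_gwas_enrichment(cats, gwas_p))
  expect_lt(pi1[["null"]], 0.05)
  expect_gt(pi1[["mix25"]], 0.20)
  expect_lt(pi1[["mix25"]], 0.30)
  expect_equal(pi1[["all_one"]], 0)
})

test_that("enrichment-ratio vs fold-change correlation behaves at the extremes", {
  set.seed(167)
  feats <- sprintf("TF%02d", 1:30)
  ts <- setNames(exp(rnorm(30)), feats)
  sh <- setNames(exp(rnorm(30)), feats)
  ratio <- log(ts / sh)
  r_id <- enrichment_ratio_vs_expression(ts, sh, ratio)
  expect_equal(r_id$rho, 1)
  r_rev <- enrichment_ratio_vs_expression(ts, sh, -ratio)
  expect_equal(r_rev$rho, -1)
  # independent tables: small |rho|
  r_null <- enrichment_ratio_vs_expression(ts, sh, setNames(rnorm(30), feats))
  expect_lt(abs(r_null$rho), 0.6)
  # non-positive OR dropped with warning
  ts2 <- ts; ts2[1] <- 0
  expect_warning(r_drop <- enrichment_ratio_vs_expression(ts2, sh, ratio),
                 "non-positive")
  expect_equal(r_drop$n, 29)
})
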