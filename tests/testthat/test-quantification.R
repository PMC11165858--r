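# eRNA region construction, read counting, normalization, detectability,
# inverse-normal transform.

test_that("eRNA regions are centered on enhancer midpoints and clipped at ends", {
  enh <- interval_set("chr1", 10000, 12000)
  r <- build_erna_regions(enh)
  expect_equal(r$midpoint, 11000L)
  expect_equal(r$start, 8000L)
  expect_equal(r$end, 14000L)
  expect_equal(r$end - r$start, 6000L)  # +/- 3 kb around the midpoint
  expect_false(r$clipped)

  # width-1 enhancer still yields a 6 kb region centred on that base
  r1 <- build_erna_regions(interval_set("chr1", 9999, 10000))
  expect_equal(r1$end - r1$start, 6000L)
  expect_equal(r1$midpoint, 9999L)

  # near the chromosome start the region is clipped and flagged
  r0 <- build_erna_regions(interval_set("chr1", 1000, 2000))
  expect_equal(r0$start, 0L)
  expect_true(r0$clipped)

  expect_error(build_erna_regions(empty_intervals()), "no enhancers")
})

test_that("coding-overlap filter honours the 1 kb extension boundary and the oracle", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", start = 50000,
                      end = 60000, strand = "+", biotype = "protein_coding",
                      tss = 50000, tes = 59999)
  mk <- function(s, e) data.frame(erna_id = "r", chrom = "chr1", start = s,
                                  end = e, stringsAsFactors = FALSE)
  expect_equal(nrow(filter_coding_overlap(mk(52000, 58000), genes)), 0L)
  # extended gene covers [49000, 61000); region starting 1001 bp past the
  # gene end is retained, touching the extension is not
  expect_equal(nrow(filter_coding_overlap(mk(61000, 67000), genes)), 1L)
  expect_equal(nrow(filter_coding_overlap(mk(60999, 66999), genes)), 0L)
  # non-coding genes are ignored
  genes_nc <- transform(genes, biotype = "lincRNA")
  expect_equal(nrow(filter_coding_overlap(mk(52000, 58000), genes_nc)), 1L)

  set.seed(61)
  L <- 10000
  regions <- random_intervals(60, L, max_w = 800)
  regions$erna_id <- sprintf("r%02d", seq_len(60))
  gs <- random_intervals(8, L, max_w = 1500)
  genes2 <- data.frame(gene_id = sprintf("g%d", 1:8), chrom = gs$chrom,
                       start = gs$start, end = gs$end, strand = "+",
                       biotype = "protein_coding", tss = gs$start,
                       tes = gs$end - 1)
  ext <- data.frame(chrom = genes2$chrom, start = pmax(0, genes2$start - 1000),
                    end = genes2$end + 1000)
  keep_oracle <- oracle_overlap_bases(regions, ext, L) == 0
  got <- filter_coding_overlap(regions, genes2)
  expect_equal(got$erna_id, regions$erna_id[keep_oracle])
})

test_that("read counting matches a brute-force assignment oracle and both multi-count policies", {
  regions <- data.frame(erna_id = c("a", "b"), chrom = "chr1",
                        start = c(0L, 6000L), end = c(6000L, 12000L),
                        stringsAsFactors = FALSE)
  reads <- interval_set("chr1", c(100, 5950, 7000), c(200, 6050, 7100))
  m <- count_reads(regions, list(s1 = reads))
  # read 2 spans the abutting boundary: counted in both regions
  expect_equal(unname(m[, "s1"]), c(2, 2))
  mf <- count_reads(regions, list(s1 = reads), multi_count = "fractional")
  expect_equal(unname(mf[, "s1"]), c(1.5, 1.5))
  expect_equal(attr(m, "library_sizes"), c(s1 = 3L))

  set.seed(67)
  L <- 10000
  regions2 <- random_intervals(15, L, max_w = 1200)
  regions2$erna_id <- sprintf("r%02d", 1:15)
  aln <- list(sA = random_intervals(500, L, max_w = 100),
              sB = random_intervals(300, L, max_w = 100))
  got <- count_reads(regions2, aln)
  for (s in names(aln)) {
    want <- vapply(seq_len(nrow(regions2)), function(i) {
      sum(aln[[s]]$start < regions2$end[i] & aln[[s]]$end > regions2$start[i])
    }, numeric(1))
    expect_equal(unname(got[, s]), want)
  }
  # invariant to read-file ordering
  aln_shuf <- lapply(aln, function(d) d[sample(nrow(d)), ])
  expect_equal(unclass(count_reads(regions2, aln_shuf)), unclass(got),
               ignore_attr = TRUE)

  expect_error(count_reads(regions2, list(aln$sA)), "named")
})

test_that("RPKM follows its defining formula and homogeneity", {
  m <- matrix(c(100, 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
  v <- rpkm(m, region_lengths = c(a = 6000, b = 6000),
            library_sizes = c(s1 = 1e6))
  expect_equal(v["a", "s1"], 100 / 6, tolerance = 1e-12)
  expect_equal(v["b", "s1"], 0)
  v10 <- rpkm(10 * m, region_lengths = c(a = 6000, b = 6000),
              library_sizes = c(s1 = 1e7))
  expect_equal(unclass(v10), unclass(v), ignore_attr = TRUE)
  expect_error(rpkm(m, region_lengths = c(a = 6000, b = 6000),
                    library_sizes = c(s1 = 0)), "library size")
})

test_that("detectability filter applies strict expressed-fraction and mean thresholds", {
  # 20-feature toy with known means and expressed fractions (10 samples)
  set.seed(71)
  n <- 10
  means <- rep(c(0.4, 0.49, 0.5, 0.6, 2), each = 4)
  fracs <- rep(c(0.5, 0.6, 1, 0.4), times = 5)
  x <- t(mapply(function(mu, fr) {
    nz <- round(fr * n)
    v <- c(rep(mu * n / max(nz, 1), nz), rep(0, n - nz))
    sample(v)
  }, means, fracs))
  rownames(x) <- sprintf("f%02d", 1:20)
  attr(x, "units") <- "RPKM"
  keep_hand <- means >= 0.5 & fracs > 0.5
  got <- detectability_filter(x, mode = "rpkm_cohort")
  expect_equal(rownames(got), rownames(x)[keep_hand])
  # exactly 50% expressed is removed; mean 0.49 everywhere-expressed is removed
  expect_false("f01" %in% rownames(got))  # frac 0.5
  expect_false("f07" %in% rownames(got))  # mean 0.49, frac 1

  # monotone in min_mean
  for (mm in c(0.3, 0.5, 1, 2)) {
    a <- rownames(detectability_filter(x, min_mean = mm))
    b <- rownames(detectability_filter(x, min_mean = mm + 0.5))
    expect_true(all(b %in% a))
  }

  # units guard
  attr(x, "units") <- "RPM"
  expect_error(detectability_filter(x, mode = "rpkm_cohort"), "units")
  expect_equal(nrow(detectability_filter(x, mode = "rpm_tcga")),
               sum(means >= 1 & fracs > 0.5))
})

test_that("inverse-normal transform applies the Blom formula and rank invariance", {
  x <- matrix(c(3, 1, 2), 1, dimnames = list("f", NULL))
  got <- inverse_normal_transform(x)
  expect_equal(unname(got[1, ]),
               qnorm((c(3, 1, 2) - 3 / 8) / (3 + 1 / 4)), tolerance = 1e-12)
  expect_equal(unname(got[1, 2]), qnorm((1 - 3 / 8) / 3.25))
  expect_equal(unname(got[1, 1]), -unname(got[1, 2]))

  # any strictly monotone transform gives identical scores
  set.seed(73)
  y <- matrix(rexp(50), 1, dimnames = list("f", NULL))
  expect_equal(inverse_normal_transform(exp(y))[1, ],
               inverse_normal_transform(y)[1, ])
  # per-feature mean ~ 0, sd ~ 1
  z <- inverse_normal_transform(matrix(rnorm(200), 2))
  expect_lt(max(abs(rowMeans(z))), 1e-10)
  expect_equal(unname(apply(z, 1, sd)), c(1, 1), tolerance = 0.05)

  # constant feature -> zeros with a warning
  cst <- matrix(5, 1, 10, dimnames = list("flat", NULL))
  expect_warning(out <- inverse_normal_transform(cst), "constant")
  expect_equal(unname(out[1, ]), rep(0, 10))
})
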