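# Independent brute-force oracles used by the unit tests. These deliberately
# share no code with the package: interval questions are answered per base on
# a small toy chromosome, exact tests by full enumeration.

# per-base coverage vector of a chromosome of length L
oracle_cover <- function(x, chrom, L) {
  v <- integer(L)
  d <- x[x$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    if (d$end[i] > d$start[i])
      v[(d$start[i] + 1):d$end[i]] <- v[(d$start[i] + 1):d$end[i]] + 1L
  }
  v
}

# bases of each interval of a covered by union of b (per-base count)
oracle_overlap_bases <- function(a, b, L) {
  vapply(seq_len(nrow(a)), function(i) {
    cov <- oracle_cover(b, a$chrom[i], L) > 0
    sum(cov[(a$start[i] + 1):a$end[i]])
  }, numeric(1))
}

# per-base support segments: bases covered by >= min_support distinct samples
oracle_support_segments <- function(peak_sets, chrom, L, min_support) {
  sup <- integer(L)
  for (s in peak_sets) sup <- sup + (oracle_cover(s, chrom, L) > 0)
  keep <- sup >= min_support
  if (!any(keep)) return(data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0)))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  data.frame(chrom = chrom, start = starts[r$values],
             end = ends[r$values])[order(starts[r$values]), ]
}

# random interval set on [0, L)
random_intervals <- function(n, L, chrom = "chrT", max_w = 400) {
  w <- sample.int(max_w, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(L - wi, 1) - 1L, integer(1))
  data.frame(chrom = chrom, start = s, end = s + w, stringsAsFactors = FALSE)
}

# HWE exact p by direct enumeration over all heterozygote counts compatible
# with the observed allele counts
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(h) - lfactorial(hr) - lfactorial(hc) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables with
# the observed margins
oracle_fisher <- function(a, b, c_, d) {
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  av <- max(0, k - m2):min(k, m1)
  pr <- stats::dhyper(av, m1, m2, k)
  sum(pr[pr <= stats::dhyper(a, m1, m2, k) * (1 + 1e-7)])
}

# partial correlation from the precision matrix of cbind(x, y, covars)
oracle_pcor <- function(x, y, covars) {
  S <- stats::cov(cbind(x, y, covars))
  P <- solve(S)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}
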