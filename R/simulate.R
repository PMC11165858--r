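# Synthetic-data generators. Every downstream stage of the pipeline is
# testable against the truth tables these functions emit; tests that claim
# "recovery" read truth only from those tables.
#
# Seeding: each generator reseeds from cfg$seed plus a fixed small offset, so
# a config reproduces byte-identical outputs regardless of call order.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic cohort in one validated list. The
#' defaults mirror the study conditions the pipeline is designed for: a
#' 154-sample paired-tissue expression cohort, 10 replicate peak samples per
#' assay, Beta-distributed imputation INFO scores, block-structured LD via a
#' first-order haplotype-copying chain, planted additive cis effects on eRNA
#' expression, target genes driven by eRNA plus tumor-purity confounding, and
#' case-control stages with a planted per-allele odds ratio.
#'
#' @param seed integer; reproduces byte-identical outputs.
#' @param chrom,chrom_length chromosome name and length (bp) of the toy genome.
#' @param n_genes,n_enhancers,gene_width,enhancer_width element counts/widths.
#' @param collision_fraction fraction of enhancers deliberately placed on a TSS
#'   to exercise the exclusion filters (ignored when `n_genes = 0`).
#' @param n_variants,ld_block_size,ld_rho,maf_range genotype structure:
#'   variants per block copy the previous haplotype allele with probability
#'   `ld_rho`, else redraw at their own MAF drawn uniformly from `maf_range`.
#' @param indel_prop proportion of variants typed as indels.
#' @param info_beta shape parameters of the Beta distribution for INFO scores.
#' @param n_samples expression-cohort size.
#' @param n_qtl,qtl_beta planted (variant, eRNA) cis effects per state.
#' @param qtl_share_frac fraction of planted effects shared between the tumor
#'   and normal states.
#' @param n_links,link_gamma planted (eRNA, gene) regulatory links.
#' @param purity_effect effect of tumor purity on target-gene expression;
#'   `erna_purity_effect` is the (smaller) purity effect on eRNA abundance.
#' @param noise_sd residual SD of latent log-abundance and gene expression.
#' @param base_log_rpkm mean latent log-RPKM of an eRNA region.
#' @param library_size mean mapped reads per sample.
#' @param half_width,gene_extension,tss_flank,window region-definition and
#'   cis-window parameters (bp), matching the analysis defaults.
#' @param n_peak_samples replicate samples per assay.
#' @param peak_jitter_sd,peak_fnr,peak_fpr peak-boundary jitter SD (bp),
#'   per-sample miss rate, and spurious-peak rate per true peak.
#' @param n_cases,n_controls,planted_or,assoc_maf,assoc_intercept case-control
#'   cohort: per-allele odds ratio planted at a variant of frequency
#'   `assoc_maf`, baseline log-odds `assoc_intercept`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom = "chr1", chrom_length = 2e6L,
                       n_genes = 20L, n_enhancers = 30L,
                       gene_width = 4000L, enhancer_width = 600L,
                       collision_fraction = 0,
                       n_variants = 400L, ld_block_size = 10L, ld_rho = 0.8,
                       maf_range = c(0.05, 0.5), indel_prop = 0.1,
                       info_beta = c(10, 1),
                       n_samples = 154L,
                       n_qtl = 10L, qtl_beta = 1, qtl_share_frac = 0.5,
                       n_links = 5L, link_gamma = 1,
                       purity_effect = 1, erna_purity_effect = 0.5,
                       noise_sd = 1, base_log_rpkm = log(2),
                       library_size = 1e6,
                       half_width = 3000L, gene_extension = 1000L,
                       tss_flank = 2500L, window = 1e6,
                       n_peak_samples = 10L,
                       peak_jitter_sd = 0, peak_fnr = 0, peak_fpr = 0,
                       n_cases = 1000L, n_controls = 1000L,
                       planted_or = 0.91, assoc_maf = 0.3,
                       assoc_intercept = qlogis(0.3)) {
  cfg <- as.list(environment())
  stopifnot(cfg$seed == round(cfg$seed),
            cfg$chrom_length > 0,
            cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
            cfg$maf_range[1] <= cfg$maf_range[2],
            cfg$ld_rho >= 0, cfg$ld_rho < 1,
            cfg$collision_fraction >= 0, cfg$collision_fraction <= 1,
            cfg$peak_fnr >= 0, cfg$peak_fnr <= 1,
            cfg$peak_fpr >= 0,
            cfg$indel_prop >= 0, cfg$indel_prop <= 1,
            cfg$planted_or > 0,
            cfg$noise_sd >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the toy genome: gene models and true enhancers
#'
#' Genes and enhancers are packed onto one chromosome with enough clearance
#' (eRNA half-width plus the larger of the TSS flank and the gene extension)
#' that every regularly placed enhancer survives the downstream exclusion
#' filters. A `collision_fraction` of enhancers is instead centred on a random
#' TSS so that the filters have something to remove.
#'
#' @param cfg a [sim_config()].
#' @return List with `genes` (gene models), `enhancers` (interval data frame
#'   with a logical `collider` column), `chrom`, `chrom_length`.
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  n_coll <- if (cfg$n_genes > 0) round(cfg$collision_fraction * cfg$n_enhancers) else 0L
  n_free <- cfg$n_enhancers - n_coll
  widths <- c(rep(cfg$gene_width, cfg$n_genes), rep(cfg$enhancer_width, n_free))
  kind <- c(rep("gene", cfg$n_genes), rep("enhancer", n_free))
  clearance <- cfg$half_width + max(cfg$gene_extension, cfg$tss_flank) + 500L
  n <- length(widths)
  slack <- cfg$chrom_length - sum(widths) - (n + 1) * clearance
  if (slack < 0)
    stop("infeasible packing: ", cfg$n_genes, " genes + ", n_free,
         " enhancers with ", clearance, " bp clearance exceed chrom_length ",
         cfg$chrom_length)
  if (n > 0) {
    ord <- sample.int(n)
    widths <- widths[ord]; kind <- kind[ord]
    extra <- as.vector(stats::rmultinom(1, slack, rep(1, n + 1)))
    gaps <- clearance + extra[seq_len(n)]
    starts <- cumsum(gaps) + cumsum(c(0L, widths[-n]))
    ends <- starts + widths
  } else starts <- ends <- integer(0)

  gi <- kind == "gene"
  genes <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), biotype = character(0))
  if (any(gi)) {
    genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(sum(gi))),
                        chrom = cfg$chrom,
                        start = as.integer(starts[gi]),
                        end = as.integer(ends[gi]),
                        strand = sample(c("+", "-"), sum(gi), replace = TRUE),
                        biotype = "protein_coding",
                        stringsAsFactors = FALSE)
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)

  ei <- kind == "enhancer"
  enh <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    collider = logical(0))
  if (any(ei) || n_coll > 0) {
    e_start <- as.integer(starts[ei]); e_end <- as.integer(ends[ei])
    collider <- rep(FALSE, sum(ei))
    if (n_coll > 0) {
      at <- sample.int(nrow(genes), n_coll, replace = TRUE)
      cs <- as.integer(genes$tss[at] - cfg$enhancer_width %/% 2)
      cs <- pmax(0L, cs)
      e_start <- c(e_start, cs); e_end <- c(e_end, cs + cfg$enhancer_width)
      collider <- c(collider, rep(TRUE, n_coll))
    }
    o <- order(e_start)
    enh <- data.frame(chrom = cfg$chrom, start = e_start[o], end = e_end[o],
                      collider = collider[o], stringsAsFactors = FALSE)
    enh$id <- sprintf("enh%03d", seq_len(nrow(enh)))
  }
  list(genes = genes, enhancers = enh,
       chrom = cfg$chrom, chrom_length = cfg$chrom_length)
}

#' Simulate replicate peak sets for one assay
#'
#' Each true enhancer yields a peak in each sample with probability
#' `1 - peak_fnr`; retained boundaries are jittered by rounded
#' Normal(0, peak_jitter_sd). Spurious peaks are added at Poisson rate
#' `peak_fpr` per true peak, placed uniformly with widths resampled from the
#' true widths.
#'
#' @param genome output of [simulate_genome()].
#' @param cfg a [sim_config()].
#' @param assay `"ATAC"` or `"H3K27ac"` (only changes the RNG stream and peak
#'   ids).
#' @param n_samples number of replicate samples.
#' @return List of interval data frames, one per sample.
#' @export
simulate_peaks <- function(genome, cfg, assay = c("ATAC", "H3K27ac"),
                           n_samples = cfg$n_peak_samples) {
  assay <- match.arg(assay)
  stopifnot(n_samples >= 1)
  set.seed(cfg$seed + 1000L * match(assay, c("ATAC", "H3K27ac")) + 7L)
  truth <- genome$enhancers
  lapply(seq_len(n_samples), function(s) {
    keep <- stats::runif(nrow(truth)) >= cfg$peak_fnr
    d <- truth[keep, c("chrom", "start", "end"), drop = FALSE]
    if (nrow(d) && cfg$peak_jitter_sd > 0) {
      d$start <- pmax(0L, d$start +
                        as.integer(round(stats::rnorm(nrow(d), 0, cfg$peak_jitter_sd))))
      d$end <- pmax(d$start + 1L, d$end +
                      as.integer(round(stats::rnorm(nrow(d), 0, cfg$peak_jitter_sd))))
    }
    n_spur <- if (cfg$peak_fpr > 0 && nrow(truth))
      stats::rpois(1, cfg$peak_fpr * nrow(truth)) else 0L
    if (n_spur > 0) {
      w <- sample(truth$end - truth$start, n_spur, replace = TRUE)
      st <- as.integer(floor(stats::runif(n_spur, 0, genome$chrom_length - w)))
      d <- rbind(d, data.frame(chrom = genome$chrom, start = st, end = st + w,
                               stringsAsFactors = FALSE))
    }
    d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
    rownames(d) <- NULL
    if (nrow(d)) d$id <- sprintf("%s_s%02d_p%04d", assay, s, seq_len(nrow(d)))
    d
  })
}

#' Simulate LD-structured diploid genotypes
#'
#' Haplotypes are generated per LD block by a first-order copying chain: the
#' first variant's allele is Bernoulli(MAF); each subsequent allele copies the
#' previous haplotype allele with probability `ld_rho`, else is redrawn at its
#' own MAF. Diploid dosage is the sum of two independent haplotypes, so every
#' variant is in Hardy-Weinberg equilibrium by construction.
#'
#' @param cfg a [sim_config()].
#' @param n_samples number of diploid samples.
#' @return A `genotype_matrix`: list with `dosage` (variants x samples integer
#'   matrix) and `variants` (per-variant metadata: id, chrom, pos, ref, alt,
#'   type, maf, info).
#' @export
simulate_genotypes <- function(cfg, n_samples = cfg$n_samples) {
  set.seed(cfg$seed + 2L)
  nv <- cfg$n_variants
  maf <- stats::runif(nv, cfg$maf_range[1], cfg$maf_range[2])
  pos <- sort(sample.int(cfg$chrom_length - 1L, nv))
  blocks <- split(seq_len(nv), (seq_len(nv) - 1L) %/% cfg$ld_block_size)
  one_haplotype_set <- function() {
    H <- matrix(0L, nv, n_samples)
    for (idx in blocks) {
      H[idx[1], ] <- stats::rbinom(n_samples, 1, maf[idx[1]])
      for (j in idx[-1]) {
        copy <- stats::runif(n_samples) < cfg$ld_rho
        fresh <- stats::rbinom(n_samples, 1, maf[j])
        H[j, ] <- ifelse(copy, H[j - 1L, ], fresh)
      }
    }
    H
  }
  dosage <- one_haplotype_set() + one_haplotype_set()
  storage.mode(dosage) <- "integer"
  type <- sample(c("SNV", "indel"), nv, replace = TRUE,
                 prob = c(1 - cfg$indel_prop, cfg$indel_prop))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  ref[type == "indel"] <- paste0(ref[type == "indel"], "T")
  info <- stats::rbeta(nv, cfg$info_beta[1], cfg$info_beta[2])
  variants <- data.frame(variant_id = sprintf("var%05d", seq_len(nv)),
                         chrom = cfg$chrom, pos = as.integer(pos),
                         ref = ref, alt = unname(alt), type = type,
                         maf = maf, info = info, stringsAsFactors = FALSE)
  dimnames(dosage) <- list(variants$variant_id,
                           sprintf("S%03d", seq_len(n_samples)))
  genotype_matrix(dosage, variants)
}

#' Pick planted cis QTL effects
#'
#' Chooses `n` (variant, eRNA region) pairs with the variant inside the cis
#' window of the region and a drawn MAF of at least `min_maf` (so planted
#' variants comfortably pass QC). Regions are drawn without replacement.
#'
#' @param geno a `genotype_matrix`.
#' @param regions eRNA region data frame (see [build_erna_regions()]).
#' @param cfg a [sim_config()].
#' @param n number of planted effects.
#' @param beta planted additive effect per alt allele.
#' @param min_maf minimum drawn MAF of a planted variant.
#' @return Data frame with columns erna_id, variant_id, beta.
#' @export
plant_qtls <- function(geno, regions, cfg, n = cfg$n_qtl, beta = cfg$qtl_beta,
                       min_maf = 0.1) {
  stopifnot(n <= nrow(regions))
  pick_regions <- sample(regions$erna_id, n)
  used <- character(0)  # one distinct variant per planted effect
  out <- lapply(pick_regions, function(rid) {
    r <- regions[regions$erna_id == rid, ]
    v <- geno$variants
    d <- pmax(0, r$start - v$pos, v$pos - (r$end - 1L))
    ok <- which(d <= cfg$window & v$maf >= min_maf &
                  !(v$variant_id %in% used))
    if (!length(ok)) {
      warning("no eligible variant in cis of region ", rid, "; effect not planted")
      return(NULL)
    }
    vid <- v$variant_id[ok[sample.int(length(ok), 1)]]
    used <<- c(used, vid)
    data.frame(erna_id = rid, variant_id = vid,
               beta = beta, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate eRNA and target-gene expression with planted effects
#'
#' Latent log-abundance of region e in sample s is
#' `base + beta * dosage + covariate effects + purity effect + N(0, noise_sd)`;
#' read counts are Poisson with mean `exp(latent) * length_kb * library/1e6`,
#' so the expected RPKM equals `exp(latent)`. Target-gene expression is
#' `5 + gamma * eRNA_RPKM + purity_effect * purity + N(0, noise_sd)`, which
#' plants both real links and purity-only confounded pairs.
#'
#' @param geno a `genotype_matrix` for the same samples.
#' @param regions eRNA region data frame.
#' @param genes gene models (targets are drawn from these).
#' @param cfg a [sim_config()].
#' @param qtl_table planted effects from [plant_qtls()] (NULL for an all-null
#'   cohort).
#' @param link_table planted (erna_id, gene_id, gamma) links; NULL to plant
#'   `cfg$n_links` at random among cis gene/region pairs.
#' @param covariate_effects named numeric vector of latent-scale effects for
#'   age (per year from 60), sex, batch.
#' @param emit_reads if TRUE, also return per-sample read intervals (each read
#'   placed uniformly within its region, plus background reads in the gaps)
#'   so the counting path can be exercised; library sizes then equal the
#'   number of emitted reads.
#' @param seed_offset RNG offset from `cfg$seed` (use different offsets for
#'   tumor and normal states).
#' @return List with `counts`, `rpkm`, `gene_expr` (matrices), `covariates`
#'   (data frame with age, sex, batch, purity, stage), `library_sizes`,
#'   `reads` (list of interval data frames or NULL), `qtl_table`, `link_table`.
#' @export
simulate_expression <- function(geno, regions, genes, cfg,
                                qtl_table = NULL, link_table = NULL,
                                covariate_effects = c(age = 0.01, sex = 0.1,
                                                      batch = 0.3),
                                emit_reads = FALSE, seed_offset = 3L) {
  set.seed(cfg$seed + seed_offset)
  samples <- colnames(geno$dosage)
  n <- length(samples)
  covar <- data.frame(age = stats::rnorm(n, 60, 8),
                      sex = stats::rbinom(n, 1, 0.5),
                      batch = stats::rbinom(n, 1, 0.5),
                      purity = stats::rbeta(n, 6, 2),
                      stage = sample(1:4, n, replace = TRUE),
                      row.names = samples)
  nr <- nrow(regions)
  A <- matrix(cfg$base_log_rpkm, nr, n,
              dimnames = list(regions$erna_id, samples))
  A <- A + outer(rep(1, nr), covariate_effects["age"] * (covar$age - 60) +
                   covariate_effects["sex"] * covar$sex +
                   covariate_effects["batch"] * covar$batch +
                   cfg$erna_purity_effect * covar$purity)
  if (!is.null(qtl_table)) {
    for (i in seq_len(nrow(qtl_table))) {
      A[qtl_table$erna_id[i], ] <- A[qtl_table$erna_id[i], ] +
        qtl_table$beta[i] * geno$dosage[qtl_table$variant_id[i], ]
    }
  }
  if (cfg$noise_sd > 0) A <- A + matrix(stats::rnorm(nr * n, 0, cfg$noise_sd), nr, n)
  lib <- round(stats::runif(n, 0.8, 1.2) * cfg$library_size)
  len_kb <- (regions$end - regions$start) / 1000
  lambda <- exp(A) * outer(len_kb, lib / 1e6)
  counts <- matrix(stats::rpois(nr * n, lambda), nr, n,
                   dimnames = dimnames(A))
  counts_m <- structure(counts, library_sizes = stats::setNames(lib, samples),
                        region_lengths = stats::setNames(
                          as.integer(regions$end - regions$start), regions$erna_id),
                        units = "counts")
  rpkm_m <- rpkm(counts_m)

  if (is.null(link_table) && cfg$n_links > 0 && nrow(genes) > 0) {
    pairs <- expand.grid(erna_id = regions$erna_id, gene_id = genes$gene_id,
                         stringsAsFactors = FALSE)
    tssd <- mapply(function(e, g) {
      r <- regions[regions$erna_id == e, ]; t <- genes$tss[genes$gene_id == g]
      max(0, r$start - t, t - (r$end - 1L))
    }, pairs$erna_id, pairs$gene_id)
    pairs <- pairs[tssd <= cfg$window, , drop = FALSE]
    # at most one planted link per gene so links are unambiguous
    pairs <- pairs[!duplicated(pairs$gene_id), , drop = FALSE]
    if (nrow(pairs) > 0) {
      take <- pairs[sample(nrow(pairs), min(cfg$n_links, nrow(pairs))), ,
                    drop = FALSE]
      link_table <- data.frame(take, gamma = cfg$link_gamma,
                               stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  gene_expr <- NULL
  if (nrow(genes) > 0) {
    gene_expr <- matrix(5 + cfg$purity_effect * rep(covar$purity, each = nrow(genes)),
                        nrow(genes), n, dimnames = list(genes$gene_id, samples))
    if (!is.null(link_table) && nrow(link_table)) {
      for (i in seq_len(nrow(link_table))) {
        gene_expr[link_table$gene_id[i], ] <- gene_expr[link_table$gene_id[i], ] +
          link_table$gamma[i] * rpkm_m[link_table$erna_id[i], ]
      }
    }
    if (cfg$noise_sd > 0)
      gene_expr <- gene_expr + matrix(stats::rnorm(length(gene_expr), 0, cfg$noise_sd),
                                      nrow(gene_expr), ncol(gene_expr))
  }

  reads <- NULL
  if (emit_reads) {
    read_len <- 100L
    gaps <- complement_intervals(regions, cfg$chrom, cfg$chrom_length)
    reads <- lapply(seq_len(n), function(s) {
      in_region <- lapply(seq_len(nr), function(i) {
        k <- counts[i, s]
        if (k == 0) return(NULL)
        w <- regions$end[i] - regions$start[i]
        st <- regions$start[i] +
          as.integer(floor(stats::runif(k, 0, max(1, w - read_len))))
        data.frame(chrom = regions$chrom[i], start = st,
                   end = pmin(st + read_len, regions$end[i]),
                   stringsAsFactors = FALSE)
      })
      n_bg <- max(0L, lib[s] - sum(counts[, s]))
      bg <- NULL
      if (n_bg > 0 && nrow(gaps) > 0) {
        gw <- gaps$end - gaps$start
        gi <- sample.int(nrow(gaps), n_bg, replace = TRUE, prob = gw)
        st <- gaps$start[gi] +
          as.integer(floor(stats::runif(n_bg, 0, pmax(1, gw[gi] - read_len))))
        bg <- data.frame(chrom = gaps$chrom[gi], start = st,
                         end = pmin(st + read_len, gaps$end[gi]),
                         stringsAsFactors = FALSE)
      }
      d <- do.call(rbind, c(in_region, list(bg)))
      if (is.null(d)) d <- empty_intervals()
      d[order(d$chrom, d$start), , drop = FALSE]
    })
    names(reads) <- samples
  }

  list(counts = counts_m, rpkm = rpkm_m, gene_expr = gene_expr,
       covariates = covar, library_sizes = stats::setNames(lib, samples),
       reads = reads, qtl_table = qtl_table, link_table = link_table)
}

# Intervals of the chromosome not covered by `regions` (used to place
# background reads).
complement_intervals <- function(regions, chrom, chrom_length) {
  m <- merge_intervals(regions)
  m <- m[m$chrom == chrom, , drop = FALSE]
  bounds <- c(0L, rbind(m$start, m$end), chrom_length)
  starts <- bounds[seq(1, length(bounds), by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  ok <- ends > starts
  data.frame(chrom = chrom, start = as.integer(starts[ok]),
             end = as.integer(ends[ok]), stringsAsFactors = FALSE)
}

#' Simulate a case-control cohort with a planted per-allele odds ratio
#'
#' Covariates (sex, age, smoking, drinking) are drawn from fixed
#' distributions; the genotype is Binomial(2, assoc_maf); disease probability
#' is `plogis(intercept + log(planted_or) * dosage + covariate terms)`.
#' Sampling continues in batches until the case and control quotas are both
#' reached.
#'
#' @param cfg a [sim_config()].
#' @param stage stage index (changes the RNG stream and the stage label).
#' @param n_cases,n_controls quotas.
#' @return Data frame with phenotype (0/1), dosage, sex, age, smoking,
#'   drinking, stage.
#' @export
simulate_case_control <- function(cfg, stage = 1L,
                                  n_cases = cfg$n_cases,
                                  n_controls = cfg$n_controls) {
  set.seed(cfg$seed + 100L + stage)
  cases <- controls <- NULL
  got_cases <- got_controls <- 0L
  tries <- 0L
  while (got_cases < n_cases || got_controls < n_controls) {
    tries <- tries + 1L
    if (tries > 60L)
      stop("could not reach case/control quotas: planted prevalence degenerate")
    m <- 2L * (n_cases + n_controls)
    d <- data.frame(dosage = stats::rbinom(m, 2, cfg$assoc_maf),
                    sex = stats::rbinom(m, 1, 0.5),
                    age = stats::rnorm(m, 60, 10),
                    smoking = stats::rbinom(m, 1, 0.3),
                    drinking = stats::rbinom(m, 1, 0.3))
    lp <- cfg$assoc_intercept + log(cfg$planted_or) * d$dosage +
      0.2 * d$sex + 0.01 * (d$age - 60) + 0.4 * d$smoking + 0.2 * d$drinking
    pr <- stats::plogis(lp)
    if (all(pr < 1e-12) || all(pr > 1 - 1e-12))
      stop("planted prevalence numerically 0 or 1")
    d$phenotype <- stats::rbinom(m, 1, pr)
    new_cases <- d[d$phenotype == 1, , drop = FALSE]
    new_controls <- d[d$phenotype == 0, , drop = FALSE]
    take_ca <- utils::head(new_cases, n_cases - got_cases)
    take_co <- utils::head(new_controls, n_controls - got_controls)
    cases <- rbind(cases, take_ca); controls <- rbind(controls, take_co)
    got_cases <- nrow(cases); got_controls <- nrow(controls)
  }
  out <- rbind(cases, controls)
  out$stage <- stage
  rownames(out) <- NULL
  out
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits GT genotypes (`0/0`, `0/1`, `1/1`, `./.`) and an `INFO_SCORE` INFO
#' key, in position order, so the file re-parses through
#' [read_vcf_genotypes()].
#'
#' @param geno a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  v <- geno$variants
  o <- order(v$chrom, v$pos)
  v <- v[o, , drop = FALSE]
  dos <- geno$dosage[o, , drop = FALSE]
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow(dos), ncol(dos))
  gt[is.na(dos)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=INFO_SCORE,Number=1,Type=Float,Description=\"Imputation confidence score\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(dos)), collapse = "\t"))
  body <- paste(v$chrom, v$pos + 1L, v$variant_id, v$ref, v$alt, ".", "PASS",
                sprintf("INFO_SCORE=%.4f", v$info), "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
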