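# End-to-end demonstration pipeline on synthetic data: simulate -> annotate
# enhancers -> quantify -> QC -> map QTLs per state -> sharing -> target
# links -> enrichment -> case-control association, with a machine-readable
# report.

#' Run the full pipeline on one synthetic cohort
#'
#' Simulates a genome, replicate peak sets for both assays in both tissue
#' states, LD-structured genotypes, eRNA/gene expression with planted cis
#' effects (partially shared between states), and two case-control stages;
#' then runs every analysis stage and collects counts and headline statistics
#' in a report. Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param fdr QTL significance threshold.
#' @param use_reads if TRUE, quantification goes through emitted per-read
#'   intervals and [count_reads()]; otherwise the simulated count matrices
#'   are used directly (the read path is exercised separately at small scale).
#' @param out_dir optional directory; when given, intermediates (enhancer BED,
#'   genotype VCF, gene GTF, QTL tables, report JSON) are written there.
#' @return List with `report` plus all intermediate objects (genome, truth,
#'   enhancers, regions, qtl, sharing, links, enrichment, association).
#' @export
run_pipeline <- function(cfg = sim_config(), fdr = 0.05, use_reads = FALSE,
                         out_dir = NULL) {
  genome <- simulate_genome(cfg)
  geno <- simulate_genotypes(cfg)

  # truth regions from enhancers that are meant to survive the filters
  free_enh <- genome$enhancers[!genome$enhancers$collider, , drop = FALSE]
  truth_regions <- build_erna_regions(free_enh, half_width = cfg$half_width,
                                      chrom_length = cfg$chrom_length)
  truth_regions <- filter_coding_overlap(truth_regions, genome$genes,
                                         extension = cfg$gene_extension)

  # planted effects: a shared core plus state-specific extras
  set.seed(cfg$seed + 9L)
  n_shared <- round(cfg$qtl_share_frac * cfg$n_qtl)
  qtl_all <- plant_qtls(geno, truth_regions, cfg,
                        n = min(2 * cfg$n_qtl - n_shared, nrow(truth_regions)))
  n_all <- if (is.null(qtl_all)) 0L else nrow(qtl_all)
  if (n_all == 0) {
    qtl_tumor <- qtl_normal <- NULL
  } else {
    n_t <- min(cfg$n_qtl, n_all)
    qtl_tumor <- qtl_all[seq_len(n_t), , drop = FALSE]
    qtl_normal <- qtl_all[c(seq_len(min(n_shared, n_all)),
                            if (n_all > n_t) seq.int(n_t + 1, n_all)), ,
                          drop = FALSE]
  }

  states <- list(
    tumor = list(qtl = qtl_tumor, seed_offset = 3L),
    normal = list(qtl = qtl_normal, seed_offset = 4L))

  per_state <- lapply(names(states), function(st) {
    sdef <- states[[st]]
    expr <- simulate_expression(geno, truth_regions, genome$genes, cfg,
                                qtl_table = sdef$qtl,
                                emit_reads = use_reads,
                                seed_offset = sdef$seed_offset)
    atac <- simulate_peaks(genome, cfg, "ATAC")
    h3k <- simulate_peaks(genome, cfg, "H3K27ac")
    enh <- annotate_enhancers(atac, h3k, genome$genes,
                              tss_flank = cfg$tss_flank)
    regions <- build_erna_regions(enh, half_width = cfg$half_width,
                                  chrom_length = cfg$chrom_length)
    regions <- filter_coding_overlap(regions, genome$genes,
                                     extension = cfg$gene_extension)
    if (use_reads) {
      counts <- count_reads(regions, expr$reads)
      mat <- rpkm(counts)
    } else {
      # match recovered regions to simulated truth regions by coordinates
      idx <- match(region_key(regions), region_key(truth_regions))
      if (anyNA(idx))
        stop("recovered regions do not match simulated regions; ",
             "run with use_reads = TRUE when peak noise is enabled")
      mat <- expr$rpkm[truth_regions$erna_id[idx], , drop = FALSE]
      rownames(mat) <- regions$erna_id
    }
    detect <- detectability_filter(mat, mode = "rpkm_cohort")
    norm <- suppressWarnings(inverse_normal_transform(detect))
    covar <- cbind(age = expr$covariates$age, sex = expr$covariates$sex,
                   batch = expr$covariates$batch,
                   stage = expr$covariates$stage)
    rownames(covar) <- rownames(expr$covariates)
    qcd <- qc_filter(geno)
    qtl <- map_ernaqtl(norm, qcd, regions, covariates = covar,
                       window = cfg$window, fdr = fdr, state = st)
    # translate planted truth into recovered region ids
    truth_ids <- truth_regions$erna_id
    rec_of_truth <- regions$erna_id[match(region_key(truth_regions),
                                          region_key(regions))]
    planted <- sdef$qtl
    if (!is.null(planted))
      planted$erna_id <- rec_of_truth[match(planted$erna_id, truth_ids)]
    list(state = st, expr = expr, enhancers = enh, regions = regions,
         detect = detect, qtl = qtl, planted = planted, geno_qc = qcd)
  })
  names(per_state) <- names(states)

  sig <- lapply(per_state, function(s) s$qtl[s$qtl$significant, , drop = FALSE])
  sharing <- classify_qtl_sharing(sig$tumor, sig$normal)

  tum <- per_state$tumor
  links <- link_targets(tum$detect, tum$expr$gene_expr, tum$regions,
                        genome$genes,
                        covars = stats::setNames(tum$expr$covariates$purity,
                                                 rownames(tum$expr$covariates)),
                        window = cfg$window)

  # enrichment demo: are tumor QTL variants enriched inside true enhancers?
  v <- geno$variants
  enh_member <- v$variant_id[coverage_by(
    data.frame(chrom = v$chrom, start = v$pos, end = v$pos + 1L),
    genome$enhancers) > 0]
  qtl_vars <- unique(sig$tumor$variant_id)
  pool_ids <- setdiff(v$variant_id, qtl_vars)
  annot <- data.frame(variant_id = v$variant_id, maf = v$maf,
                      ld_proxy_count = 0L, variant_type = v$type,
                      stringsAsFactors = FALSE)
  enrich <- NULL
  if (length(qtl_vars) >= 2) {
    signal <- annotate_signal(qtl_vars, annot)
    ctrl <- suppressWarnings(
      match_controls(signal, annot[annot$variant_id %in% pool_ids, ],
                     seed = cfg$seed + 17L))
    enrich <- fisher_enrichment(qtl_vars, ctrl,
                                list(in_enhancer = enh_member))
  }

  stage1 <- simulate_case_control(cfg, stage = 1L)
  stage2 <- simulate_case_control(cfg, stage = 2L)
  assoc <- combine_stages(list(stage1, stage2), model = "additive")

  report <- list(
    seed = cfg$seed,
    n_true_enhancers = nrow(genome$enhancers),
    n_enhancers = stats::setNames(
      vapply(per_state, function(s) nrow(s$enhancers), 0L), names(per_state)),
    n_erna_regions = stats::setNames(
      vapply(per_state, function(s) nrow(s$regions), 0L), names(per_state)),
    n_detectable = stats::setNames(
      vapply(per_state, function(s) nrow(s$detect), 0L), names(per_state)),
    n_tested_pairs = stats::setNames(
      vapply(per_state, function(s) nrow(s$qtl), 0L), names(per_state)),
    n_significant = stats::setNames(
      vapply(sig, nrow, 0L), names(sig)),
    sharing = sharing$summary,
    n_links = if (is.null(links$links)) 0L else nrow(links$links),
    enrichment_or = if (!is.null(enrich)) enrich$or_ else NA_real_,
    assoc_or = stats::setNames(assoc$or_, assoc$method))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bed(per_state$tumor$enhancers,
              file.path(out_dir, "enhancers_tumor.bed"))
    write_bed(per_state$normal$enhancers,
              file.path(out_dir, "enhancers_normal.bed"))
    write_gtf(genome$genes, file.path(out_dir, "genes.gtf"))
    write_vcf(geno, file.path(out_dir, "genotypes.vcf"))
    utils::write.table(per_state$tumor$qtl,
                       file.path(out_dir, "qtl_tumor.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(per_state$normal$qtl,
                       file.path(out_dir, "qtl_normal.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(report = report, genome = genome, geno = geno,
       truth = list(regions = truth_regions, qtl = states,
                    enhancers = genome$enhancers),
       states = per_state, sharing = sharing, links = links,
       enrichment = enrich, association = assoc)
}

#' Configuration for the truth-recovery demonstration
#'
#' A small, fully deterministic-friendly variant of [sim_config()] used to
#' show exact recovery of planted structure: zero peak noise, LD-free
#' genotypes (so planted variants are the only truly associated ones), a few
#' strong planted effects, and a compact genome.
#'
#' @param seed integer seed.
#' @return A `sim_config`.
#' @export
demo_config <- function(seed = 1L) {
  sim_config(seed = seed,
             chrom_length = 2e6L, n_genes = 8L, n_enhancers = 10L,
             collision_fraction = 0.2,
             n_variants = 150L, ld_block_size = 10L, ld_rho = 0,
             n_samples = 120L,
             n_qtl = 4L, qtl_beta = 1.2, qtl_share_frac = 0.5,
             n_links = 3L, link_gamma = 1,
             peak_jitter_sd = 0, peak_fnr = 0, peak_fpr = 0,
             n_cases = 800L, n_controls = 800L)
}
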