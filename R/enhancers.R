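# Active-enhancer annotation from replicate peak sets: reproducibility across
# samples, cross-assay confirmation, and TSS-flank exclusion.

#' Reproducible peaks across replicate samples
#'
#' Resolves "identified in at least `min_support` tissues" per base on the
#' merged union of the samples' peaks: a base is kept if covered by peaks from
#' at least `min_support` distinct samples (each sample's peaks are merged
#' first so a sample contributes at most once per base). This is robust to
#' boundary jitter and independent of input ordering; output is trimmed to the
#' supported sub-segments.
#'
#' @param peak_sets list of interval data frames, one per replicate sample of
#'   a single assay.
#' @param min_support minimum number of distinct supporting samples.
#' @return Merged interval data frame of supported segments.
#' @export
reproducible_peaks <- function(peak_sets, min_support = 2) {
  if (length(peak_sets) < min_support)
    stop("need at least min_support = ", min_support,
         " peak sets, got ", length(peak_sets))
  merged <- lapply(peak_sets, merge_intervals)
  ev <- do.call(rbind, lapply(merged, function(d) {
    if (nrow(d) == 0) return(NULL)
    data.frame(chrom = d$chrom, pos = c(d$start, d$end),
               delta = rep(c(1L, -1L), each = nrow(d)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ev)) return(empty_intervals())
  out <- lapply(split(ev, ev$chrom), function(d) {
    s <- rowsum(d$delta, d$pos)               # net delta per breakpoint
    pos <- as.integer(rownames(s))
    o <- order(pos)
    pos <- pos[o]
    cov <- cumsum(s[o])
    k <- length(pos)
    keep <- cov[-k] >= min_support
    if (!any(keep)) return(NULL)
    data.frame(chrom = d$chrom[1], start = pos[-k][keep], end = pos[-1][keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_intervals())
  merge_intervals(out)
}

#' Candidate enhancers from assay intersection
#'
#' Retains accessibility (ATAC) intervals having at least 1 bp overlap with
#' any H3K27ac interval. The ATAC interval is reported by default
#' (accessibility defines the element, H3K27ac confirms activity); set
#' `report = "overlap"` to get the overlap segments instead.
#'
#' @param atac,h3k27ac reproducible-peak interval sets.
#' @param report passed to [intersect_intervals()].
#' @return Interval data frame of candidate enhancers.
#' @export
candidate_enhancers <- function(atac, h3k27ac, report = c("a", "overlap")) {
  intersect_intervals(atac, h3k27ac, min_overlap = 1, report = match.arg(report))
}

#' Drop candidates near transcription start sites
#'
#' Removes any candidate overlapping the window `[tss - flank, tss + flank]`
#' of any gene (whole-candidate removal on any overlap, no trimming: peaks are
#' excluded, not clipped). A candidate touching the flank by a single base is
#' removed.
#'
#' @param candidates interval data frame.
#' @param genes gene models carrying a `tss` column.
#' @param flank flank half-width in bp (default 2500).
#' @return Retained candidates, with attribute `n_removed`.
#' @export
exclude_tss_flanks <- function(candidates, genes, flank = 2500) {
  if (nrow(candidates) == 0 || nrow(genes) == 0)
    return(structure(candidates, n_removed = 0L))
  windows <- data.frame(chrom = genes$chrom,
                        start = pmax(0L, as.integer(genes$tss - flank)),
                        end = as.integer(genes$tss + flank + 1L),
                        stringsAsFactors = FALSE)
  hit <- coverage_by(candidates, windows) > 0
  structure(candidates[!hit, , drop = FALSE], n_removed = sum(hit))
}

#' Annotate active enhancers from replicate peak sets
#'
#' Full annotation pipeline for one tissue state: reproducible peaks per
#' assay, assay intersection, TSS-flank exclusion.
#'
#' @param atac_sets,h3k27ac_sets lists of per-sample interval data frames.
#' @param genes gene models.
#' @param min_support minimum supporting samples per assay.
#' @param tss_flank TSS exclusion half-width in bp.
#' @param report which interval the assay intersection reports.
#' @return Interval data frame of enhancers.
#' @export
annotate_enhancers <- function(atac_sets, h3k27ac_sets, genes,
                               min_support = 2, tss_flank = 2500,
                               report = c("a", "overlap")) {
  atac <- reproducible_peaks(atac_sets, min_support)
  h3k <- reproducible_peaks(h3k27ac_sets, min_support)
  cand <- candidate_enhancers(atac, h3k, report = match.arg(report))
  exclude_tss_flanks(cand, genes, flank = tss_flank)
}
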