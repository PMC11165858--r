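# eRNA quantification: region definition around enhancer midpoints, coding
# exclusion, read counting, RPKM/RPM normalization, detectability filtering,
# and rank-based inverse-normal transformation for QTL mapping.

#' Build eRNA-transcribing regions around enhancer midpoints
#'
#' Each enhancer yields the region `[mid - half_width, mid + half_width)`
#' where `mid = floor((start + end) / 2)`. Regions running off a chromosome
#' end are clipped and flagged. Duplicate coordinates are deduplicated
#' (overlapping regions are deliberately not merged: one region per enhancer).
#' Ids are assigned deterministically in coordinate order.
#'
#' @param enhancers interval data frame.
#' @param half_width region half-width in bp (default 3000).
#' @param chrom_length optional chromosome length for right-end clipping.
#' @return Data frame with erna_id, chrom, start, end, midpoint, clipped.
#' @export
build_erna_regions <- function(enhancers, half_width = 3000, chrom_length = NULL) {
  if (nrow(enhancers) == 0) stop("no enhancers supplied")
  mid <- (enhancers$start + enhancers$end) %/% 2L
  start <- mid - as.integer(half_width)
  end <- mid + as.integer(half_width)
  clipped <- start < 0
  start <- pmax(0L, start)
  if (!is.null(chrom_length)) {
    clipped <- clipped | end > chrom_length
    end <- pmin(end, as.integer(chrom_length))
  }
  out <- data.frame(chrom = enhancers$chrom, start = as.integer(start),
                    end = as.integer(end), midpoint = as.integer(mid),
                    clipped = clipped, stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("chrom", "start", "end")]), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  out <- cbind(erna_id = sprintf("eRNA_%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Exclude eRNA regions overlapping protein-coding genes
#'
#' Removes any region with at least 1 bp overlap with a protein-coding gene
#' extended by `extension` bp beyond both the TSS and the TES.
#'
#' @param regions eRNA region data frame.
#' @param genes gene models with a `biotype` column.
#' @param extension gene extension in bp (default 1000).
#' @return Surviving regions, with attribute `n_removed`.
#' @export
filter_coding_overlap <- function(regions, genes, extension = 1000) {
  pc <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  if (nrow(regions) == 0 || nrow(pc) == 0)
    return(structure(regions, n_removed = 0L))
  ext <- data.frame(chrom = pc$chrom,
                    start = pmax(0L, as.integer(pc$start - extension)),
                    end = as.integer(pc$end + extension),
                    stringsAsFactors = FALSE)
  hit <- coverage_by(regions, ext) > 0
  structure(regions[!hit, , drop = FALSE], n_removed = sum(hit))
}

#' Count reads per eRNA region
#'
#' A read is assigned to a region if it overlaps by at least 1 bp. A read
#' overlapping k > 1 regions is counted in every overlapped region under the
#' default `"all"` policy (regions may legitimately overlap after midpoint
#' expansion), or contributes 1/k per region under `"fractional"`. Library
#' sizes are the total reads of each sample's input, not reads-in-regions,
#' matching RPKM's per-million-mapped denominator.
#'
#' @param regions eRNA region data frame.
#' @param alignments named list (sample -> interval data frame of reads).
#' @param multi_count `"all"` or `"fractional"`.
#' @return Counts matrix (regions x samples) with attributes `library_sizes`,
#'   `region_lengths`, `units = "counts"`.
#' @export
count_reads <- function(regions, alignments, multi_count = c("all", "fractional")) {
  multi_count <- match.arg(multi_count)
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    stop("alignments must be a named list (sample id -> read intervals)")
  nr <- nrow(regions)
  M <- matrix(0, nr, length(alignments),
              dimnames = list(regions$erna_id, names(alignments)))
  for (s in names(alignments)) {
    r <- alignments[[s]]
    validate_intervals(r, paste0("reads for sample ", s))
    if (nrow(r) == 0) next
    hits_per_read <- integer(nrow(r))
    cols <- vector("list", nr)
    for (i in seq_len(nr)) {
      o <- r$chrom == regions$chrom[i] &
        r$start < regions$end[i] & r$end > regions$start[i]
      cols[[i]] <- o
      if (multi_count == "fractional") hits_per_read <- hits_per_read + o
    }
    for (i in seq_len(nr)) {
      M[i, s] <- if (multi_count == "all") sum(cols[[i]])
      else sum(1 / hits_per_read[cols[[i]]])
    }
  }
  structure(M,
            library_sizes = vapply(alignments, nrow, 0L),
            region_lengths = stats::setNames(
              as.integer(regions$end - regions$start), regions$erna_id),
            units = "counts")
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / (length_kb * library_size / 1e6)`. Invariant to a common
#' scaling of counts and library sizes.
#'
#' @param counts counts matrix from [count_reads()] (or carrying the same
#'   attributes).
#' @param region_lengths,library_sizes overrides for the matrix attributes.
#' @return RPKM matrix with `units = "RPKM"`.
#' @export
rpkm <- function(counts, region_lengths = attr(counts, "region_lengths"),
                 library_sizes = attr(counts, "library_sizes")) {
  if (is.null(region_lengths) || is.null(library_sizes))
    stop("region lengths and library sizes are required")
  if (any(library_sizes <= 0)) stop("zero or negative library size")
  if (any(region_lengths <= 0)) stop("zero or negative region length")
  v <- counts / outer(region_lengths / 1000, library_sizes / 1e6)
  structure(v, library_sizes = library_sizes, region_lengths = region_lengths,
            units = "RPKM", dimnames = dimnames(counts))
}

#' Reads per million mapped reads
#'
#' @inheritParams rpkm
#' @return RPM matrix with `units = "RPM"`.
#' @export
rpm <- function(counts, library_sizes = attr(counts, "library_sizes")) {
  if (is.null(library_sizes)) stop("library sizes are required")
  if (any(library_sizes <= 0)) stop("zero or negative library size")
  v <- sweep(counts, 2, library_sizes / 1e6, "/")
  structure(v, library_sizes = library_sizes,
            region_lengths = attr(counts, "region_lengths"),
            units = "RPM", dimnames = dimnames(counts))
}

#' Keep detectable eRNAs
#'
#' A feature is detectable if its mean expression is at least `min_mean` AND
#' it is non-zero in strictly more than `min_frac_samples` of samples
#' ("expressed in more than 50% of samples": a feature expressed in exactly
#' half of the samples is removed). Mode defaults: RPKM cohort
#' `min_mean = 0.5`; RPM (consortium-style) `min_mean = 1`.
#'
#' @param expr expression matrix (RPKM or RPM).
#' @param min_mean minimum mean expression (NULL for the mode default).
#' @param min_frac_samples expressed-fraction threshold (strict inequality).
#' @param mode `"rpkm_cohort"` or `"rpm_tcga"`.
#' @return Filtered matrix (attributes subset accordingly).
#' @export
detectability_filter <- function(expr, min_mean = NULL, min_frac_samples = 0.5,
                                 mode = c("rpkm_cohort", "rpm_tcga")) {
  mode <- match.arg(mode)
  if (is.null(min_mean)) min_mean <- if (mode == "rpkm_cohort") 0.5 else 1.0
  units <- attr(expr, "units")
  want <- if (mode == "rpkm_cohort") "RPKM" else "RPM"
  if (!is.null(units) && units != want)
    stop("expression units '", units, "' do not match mode ", mode,
         " (expected ", want, ")")
  keep <- rowMeans(expr) >= min_mean & rowMeans(expr > 0) > min_frac_samples
  out <- expr[keep, , drop = FALSE]
  rl <- attr(expr, "region_lengths")
  structure(out, library_sizes = attr(expr, "library_sizes"),
            region_lengths = if (!is.null(rl)) rl[rownames(out)] else NULL,
            units = units)
}

#' Rank-based inverse-normal transform
#'
#' Per feature, values are replaced by `qnorm((rank - 3/8) / (n + 1/4))`
#' (Blom offset) with average ranks for ties — the standard normalization for
#' molecular QTL mapping, invariant to any strictly monotone transform of the
#' input. Constant features become all zeros with a warning.
#'
#' @param expr expression matrix (features x samples), n >= 3 samples.
#' @return Matrix of normalized scores with `units = "normalized"`.
#' @export
inverse_normal_transform <- function(expr) {
  n <- ncol(expr)
  if (n < 3) stop("inverse-normal transform needs at least 3 samples")
  out <- t(apply(expr, 1, function(x) {
    if (length(unique(x)) == 1L) return(rep(0, n))
    stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  }))
  const <- apply(expr, 1, function(x) length(unique(x)) == 1L)
  if (any(const))
    warning(sum(const), " constant feature(s) set to all-zero scores: ",
            paste(utils::head(rownames(expr)[const], 5), collapse = ", "))
  dimnames(out) <- dimnames(expr)
  structure(out, units = "normalized")
}
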