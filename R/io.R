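# Readers and writers for the plain-text formats the pipeline touches.
# BED is parsed here (the package owns the 0-based half-open contract and the
# per-line error reporting); GTF is read through rtracklayer and converted to
# 0-based half-open on the way in.

#' Read a BED3+ file
#'
#' Parses a tab-separated BED file with 0-based half-open semantics. Columns
#' 4-6 become `id`, `score`, `strand`; any further columns are retained as
#' `extra1`, `extra2`, ... Track and comment lines are skipped.
#'
#' @param path path to a BED file.
#' @return Interval data frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 tab-separated fields")
  if (length(unique(nf)) > 1)
    stop("malformed BED line ", lineno[which(nf != nf[1])[1]],
         ": inconsistent field count (", nf[which(nf != nf[1])[1]],
         " vs ", nf[1], ")")
  ncol <- nf[1]
  m <- matrix(unlist(fields), ncol = ncol, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", lineno[which(is.na(start) | is.na(end))[1]],
         ": non-integer coordinates")
  bad <- which(end <= start)
  if (length(bad))
    stop("invalid BED line ", lineno[bad[1]], ": end <= start")
  x <- data.frame(chrom = m[, 1], start = start, end = end,
                  stringsAsFactors = FALSE)
  optional <- c("id", "score", "strand")
  for (j in seq_len(min(ncol, 6) - 3)) x[[optional[j]]] <- m[, 3 + j]
  if (ncol > 6) for (j in 7:ncol) x[[paste0("extra", j - 6)]] <- m[, j]
  if (!is.null(x$score)) {
    sc <- suppressWarnings(as.numeric(x$score))
    if (!anyNA(sc)) x$score <- sc
  }
  validate_intervals(x, path)
  x
}

#' Write intervals as BED
#'
#' Emits tab-separated BED with deterministic ordering (chrom lexicographic,
#' then start, then end). Optional columns `id`, `score`, `strand` and any
#' `extra*` columns are written after the three coordinates; missing values
#' become ".". Round-trips coordinates bit-exactly through [read_bed()].
#'
#' @param x interval data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- intersect(c("id", "score", "strand"), names(x))
  cols <- c("chrom", "start", "end", cols, grep("^extra", names(x), value = TRUE))
  # BED columns are positional: can't emit strand (col 6) without name/score
  if ("strand" %in% cols && !all(c("id", "score") %in% cols)) {
    if (!"id" %in% cols) x$id <- "."
    if (!"score" %in% cols) x$score <- 0
    cols <- c("chrom", "start", "end", "id", "score", "strand",
              grep("^extra", names(x), value = TRUE))
  }
  x <- x[order(x$chrom, x$start, x$end), cols, drop = FALSE]
  for (j in seq_along(x)) x[[j]][is.na(x[[j]])] <- "."
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation into gene models
#'
#' Builds one record per gene with strand-resolved TSS/TES. GTF input (read via
#' rtracklayer) is converted from 1-based inclusive to 0-based half-open;
#' BED12 input is taken as-is. On the forward strand the TSS is `start` and the
#' TES is `end - 1`; on the reverse strand the roles swap. Records without a
#' strand are an error, since the TSS would be undefined.
#'
#' @param path annotation file.
#' @param dialect `"gtf"` or `"bed12"`.
#' @param default_biotype biotype assigned when the input carries none
#'   (BED12 has no biotype field).
#' @return Data frame with columns gene_id, chrom, start, end, strand, tss,
#'   tes, biotype.
#' @export
read_gene_annotation <- function(path, dialect = c("gtf", "bed12"),
                                 default_biotype = "protein_coding") {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene")) {
      gr <- gr[gr$type == "gene"]
    } else if ("gene_id" %in% names(S4Vectors::mcols(gr))) {
      # no explicit gene features: collapse transcripts/exons per gene_id
      gr <- unlist(range(S4Vectors::split(gr, gr$gene_id)))
      gr$gene_id <- names(gr)
    } else stop("GTF has neither gene features nor gene_id attributes: ", path)
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(strand == "*"))
      stop("gene annotation record without strand: TSS undefined (gene ",
           gr$gene_id[which(strand == "*")[1]], ")")
    start0 <- BiocGenerics::start(gr) - 1L
    end0 <- BiocGenerics::end(gr)
    biotype <- gr$gene_biotype
    if (is.null(biotype)) biotype <- gr$gene_type
    if (is.null(biotype)) biotype <- rep(default_biotype, length(gr))
    out <- data.frame(gene_id = gr$gene_id,
                      chrom = as.character(GenomeInfoDb::seqnames(gr)),
                      start = start0, end = end0, strand = strand,
                      biotype = biotype, stringsAsFactors = FALSE)
  } else {
    x <- read_bed(path)
    if (!"strand" %in% names(x))
      stop("BED12 gene annotation must carry a strand column: ", path)
    if (any(x$strand == "."))
      stop("gene annotation record without strand: TSS undefined (line ",
           which(x$strand == ".")[1], ")")
    out <- data.frame(gene_id = if (!is.null(x$id)) x$id else
                        sprintf("gene%05d", seq_len(nrow(x))),
                      chrom = x$chrom, start = x$start, end = x$end,
                      strand = x$strand, biotype = default_biotype,
                      stringsAsFactors = FALSE)
  }
  out$tss <- ifelse(out$strand == "+", out$start, out$end - 1L)
  out$tes <- ifelse(out$strand == "+", out$end - 1L, out$start)
  rownames(out) <- NULL
  out
}

#' Write gene models as GTF
#'
#' Emits one `gene` feature per record, converting back to 1-based inclusive
#' coordinates, with `gene_id` and `gene_biotype` attributes. Used by the
#' synthetic-data module so simulated annotations re-parse through
#' [read_gene_annotation()].
#'
#' @param genes gene-model data frame (see [read_gene_annotation()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  lines <- sprintf(
    "%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"%s\";",
    genes$chrom, genes$start + 1L, genes$end, genes$strand,
    genes$gene_id, genes$biotype)
  writeLines(lines, path)
  invisible(path)
}
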