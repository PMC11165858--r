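# Genomic intervals are plain data frames with columns chrom, start, end.
# Coordinates are 0-based half-open (BED convention) everywhere in the package;
# GTF input is converted on read. Optional columns: id, score, strand, plus any
# extra annotation columns, which are carried along untouched.

#' Construct a set of genomic intervals
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open coordinates, `end > start`.
#' @param ... further equal-length columns (e.g. `id`, `strand`).
#' @return A data frame with one row per interval.
#' @export
interval_set <- function(chrom, start, end, ...) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.integer(start),
                  end = as.integer(end),
                  ...,
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

#' Validate an interval data frame
#'
#' Checks the invariants every interval container must satisfy: required
#' columns present, `start >= 0`, `end > start`, non-empty chromosome names.
#'
#' @param x data frame of intervals.
#' @param what label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, what = "interval set") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop(what, " must be a data frame with columns chrom, start, end")
  if (nrow(x) == 0) return(invisible(x))
  if (anyNA(x$start) || anyNA(x$end) || anyNA(x$chrom))
    stop(what, ": NA coordinates or chromosome names")
  if (any(!nzchar(x$chrom))) stop(what, ": empty chromosome name")
  if (any(x$start < 0)) stop(what, ": negative start coordinate")
  bad <- which(x$end <= x$start)
  if (length(bad))
    stop(what, ": end <= start at row ", bad[1],
         " (", x$chrom[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]], ")")
  invisible(x)
}

#' @rdname interval_set
#' @export
empty_intervals <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

# Two inputs must use the same chromosome naming convention ("chr" prefix is
# neither added nor stripped). Sharing no names at all is almost always a
# naming-convention mismatch, so it is an error rather than a silent empty
# result.
check_chrom_compat <- function(a, b, what = c("a", "b")) {
  if (nrow(a) == 0 || nrow(b) == 0) return(invisible(NULL))
  ca <- unique(a$chrom); cb <- unique(b$chrom)
  if (!any(ca %in% cb))
    stop("chromosome naming mismatch: ", what[1], " has {",
         paste(utils::head(ca, 5), collapse = ", "), "} but ", what[2],
         " has {", paste(utils::head(cb, 5), collapse = ", "), "}")
  invisible(NULL)
}

#' Merge overlapping and abutting intervals
#'
#' Returns the maximal non-overlapping cover of the input. Under the half-open
#' convention, abutting intervals (`[0,5)` and `[5,10)`) merge, because
#' downstream region logic treats coverage rather than interval identity.
#' Idempotent: `merge_intervals(merge_intervals(x))` equals
#' `merge_intervals(x)`.
#'
#' @param x interval data frame.
#' @return Interval data frame with columns chrom, start, end, sorted by
#'   (chrom, start).
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(empty_intervals())
  x <- x[order(x$chrom, x$start, x$end), c("chrom", "start", "end"), drop = FALSE]
  pieces <- lapply(split(x, x$chrom), function(d) {
    cm <- cummax(d$end)
    grp <- cumsum(c(TRUE, d$start[-1] > cm[-nrow(d)]))
    data.frame(chrom = d$chrom[1],
               start = as.integer(tapply(d$start, grp, min)),
               end = as.integer(tapply(d$end, grp, max)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Bases of each interval in `a` covered by the union of `b`. Workhorse for
# intersect_intervals() and the region-exclusion filters.
coverage_by <- function(a, b) {
  if (nrow(a) == 0) return(numeric(0))
  if (nrow(b) == 0) return(numeric(nrow(a)))
  bm <- merge_intervals(b)
  bsplit <- split(bm, bm$chrom)
  vapply(seq_len(nrow(a)), function(i) {
    d <- bsplit[[a$chrom[i]]]
    if (is.null(d)) return(0)
    sum(pmax(0L, pmin(a$end[i], d$end) - pmax(a$start[i], d$start)))
  }, numeric(1))
}

#' Intersect two interval sets
#'
#' Returns the intervals of `a` having at least `min_overlap` bases covered by
#' the union of `b` (the default 1 bp matches the usual any-overlap predicate).
#' With `report = "overlap"` the overlap segments themselves are returned
#' instead of the `a` intervals.
#'
#' @param a,b interval data frames on the same chromosome naming convention.
#' @param min_overlap minimum covered bases for an `a` interval to be retained.
#' @param report `"a"` (default) to report retained `a` intervals, `"overlap"`
#'   to report the covered segments.
#' @return Interval data frame.
#' @export
intersect_intervals <- function(a, b, min_overlap = 1, report = c("a", "overlap")) {
  report <- match.arg(report)
  validate_intervals(a, "a"); validate_intervals(b, "b")
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(if (report == "a") a[integer(0), , drop = FALSE] else empty_intervals())
  }
  check_chrom_compat(a, b)
  cov <- coverage_by(a, b)
  keep <- cov >= min_overlap
  if (report == "a") return(a[keep, , drop = FALSE])
  bm <- merge_intervals(b)
  bsplit <- split(bm, bm$chrom)
  segs <- lapply(which(keep), function(i) {
    d <- bsplit[[a$chrom[i]]]
    s <- pmax(a$start[i], d$start); e <- pmin(a$end[i], d$end)
    ok <- e > s
    data.frame(chrom = a$chrom[i], start = s[ok], end = e[ok],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  if (is.null(out)) return(empty_intervals())
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Canonical "chrom:start-end" key for a region; used to match recovered
# regions against simulated truth.
region_key <- function(x) sprintf("%s:%d-%d", x$chrom, x$start, x$end)
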