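#' Genomic intervals with 1-based inclusive coordinates
#'
#' A `genomic_interval` is a chromosome plus a start and end position in bp
#' (RefSeq-style, 1-based). Two width conventions coexist in fine-mapping
#' reports and both are supported via `kind`:
#'
#' * `"marker_bounded"` — the endpoints are flanking marker positions and the
#'   locus lies in the open interior; the width is `end - start` (this is how
#'   candidate-interval sizes such as "87 kb" are printed).
#' * `"feature"` — the endpoints are the first and last base of a sequence
#'   feature; the width is `end - start + 1` (this is how a 115-bp promoter
#'   deletion spanning -599..-485 is counted).
#'
#' @param chrom chromosome name.
#' @param start_bp,end_bp integer positions, `start_bp <= end_bp`.
#' @param kind `"marker_bounded"` or `"feature"`.
#' @return an object of class `genomic_interval`.
#' @examples
#' genomic_interval("7A", 674019191, 674106327)
#' @export
genomic_interval <- function(chrom, start_bp, end_bp,
                             kind = c("marker_bounded", "feature")) {
  kind <- match.arg(kind)
  assert_that(length(chrom) == 1 && length(start_bp) == 1 && length(end_bp) == 1,
              "genomic_interval() takes scalar chrom/start/end")
  start_bp <- as.numeric(start_bp); end_bp <- as.numeric(end_bp)
  assert_that(is.finite(start_bp) && is.finite(end_bp),
              "interval coordinates must be finite")
  assert_that(start_bp <= end_bp,
              "interval start (%s) must be <= end (%s)", start_bp, end_bp)
  structure(list(chrom = as.character(chrom), start_bp = start_bp,
                 end_bp = end_bp, kind = kind),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s interval> %s:%s-%s (%s)\n", x$kind, x$chrom,
              format(x$start_bp, big.mark = ","),
              format(x$end_bp, big.mark = ","),
              format_bp(interval_width(x))))
  invisible(x)
}

is_interval <- function(x) inherits(x, "genomic_interval")

#' Width of a genomic interval
#'
#' @param interval a [genomic_interval()].
#' @param convention `"between_markers"` (width `end - start`, used for
#'   marker-bounded candidate intervals) or `"inclusive_feature"`
#'   (`end - start + 1`, used for sequence features such as deletions).
#'   Defaults to the convention implied by the interval's `kind`.
#' @return width in bp (numeric, non-negative).
#' @examples
#' iv <- genomic_interval("7A", 674019191, 674106327)
#' interval_width(iv)                 # 87136
#' format_kb(interval_width(iv))      # "87 kb"
#' @export
interval_width <- function(interval,
                           convention = c("auto", "between_markers",
                                          "inclusive_feature")) {
  convention <- match.arg(convention)
  assert_that(is_interval(interval), "interval_width() needs a genomic_interval")
  if (convention == "auto")
    convention <- if (interval$kind == "feature") "inclusive_feature" else "between_markers"
  w <- interval$end_bp - interval$start_bp
  if (convention == "inclusive_feature") w <- w + 1
  w
}

#' Format a bp width at printed precision
#'
#' kb is rounded half-up to an integer; Mb half-up to one decimal.
#'
#' @param bp width in bp.
#' @return character scalar such as `"87 kb"` or `"8.7 Mb"`.
#' @rdname format_bp
#' @export
format_kb <- function(bp) sprintf("%d kb", as.integer(round_half_up(bp / 1e3)))

#' @rdname format_bp
#' @export
format_mb <- function(bp) sprintf("%.1f Mb", round_half_up(bp / 1e6, 1))

#' @param bp width in bp.
#' @rdname format_bp
#' @export
format_bp <- function(bp) {
  if (bp >= 1e6) format_mb(bp) else if (bp >= 1e3) format_kb(bp)
  else sprintf("%d bp", as.integer(bp))
}

#' Intersect a set of genomic intervals
#'
#' Returns the interval `[max(starts), min(ends)]` when non-empty, otherwise
#' `NULL`. All intervals must be on the same chromosome; the operation is
#' associative and commutative, so it equals a pairwise fold in any order.
#'
#' @param intervals a list of [genomic_interval()] objects (at least one).
#' @return a `genomic_interval` or `NULL` when the intersection is empty.
#' @export
intersect_intervals <- function(intervals) {
  if (is_interval(intervals)) intervals <- list(intervals)
  assert_that(length(intervals) >= 1, "intersect_intervals() needs >= 1 interval")
  assert_that(all(vapply(intervals, is_interval, logical(1))),
              "all inputs must be genomic_interval objects")
  chroms <- unique(vapply(intervals, `[[`, character(1), "chrom"))
  if (length(chroms) > 1) return(NULL)  # different chromosomes never overlap
  s <- max(vapply(intervals, `[[`, numeric(1), "start_bp"))
  e <- min(vapply(intervals, `[[`, numeric(1), "end_bp"))
  if (s > e) return(NULL)
  genomic_interval(chroms, s, e, kind = intervals[[1]]$kind)
}

# Remove exclusion zone `excl` [a,b] from marker-bounded interval `x` [L,R]
# under fencepost semantics (locus lives in the open interior of x; the
# exclusion covers its endpoints). Returns a list of 0-2 intervals whose
# endpoints remain on marker coordinates; pieces of zero width are dropped.
interval_subtract <- function(x, excl) {
  if (is.null(x)) return(list())
  if (x$chrom != excl$chrom) return(list(x))
  if (excl$end_bp <= x$start_bp || excl$start_bp >= x$end_bp) return(list(x))
  out <- list()
  if (excl$start_bp > x$start_bp)
    out <- c(out, list(genomic_interval(x$chrom, x$start_bp, excl$start_bp, x$kind)))
  if (excl$end_bp < x$end_bp)
    out <- c(out, list(genomic_interval(x$chrom, excl$end_bp, x$end_bp, x$kind)))
  out
}

#' Does an interval contain a position?
#'
#' Marker-bounded intervals carry the locus in their open interior, so the
#' default test is strict (`open = TRUE`).
#'
#' @param interval a [genomic_interval()] or `NULL` (always `FALSE`).
#' @param pos_bp position(s) in bp.
#' @param open strict inequality at the endpoints.
#' @return logical.
#' @export
interval_contains <- function(interval, pos_bp, open = TRUE) {
  if (is.null(interval)) return(FALSE)
  if (open) pos_bp > interval$start_bp & pos_bp < interval$end_bp
  else pos_bp >= interval$start_bp & pos_bp <= interval$end_bp
}
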