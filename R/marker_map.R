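#' Construct a marker map
#'
#' A marker map is a data frame with columns `name`, `chrom`, `pos_bp` and
#' optionally `pos_cM`, ordered by chromosome and physical position. Marker
#' names must be unique and physical positions strictly increasing within a
#' chromosome; genetic positions, when present, must be non-decreasing with
#' physical position. When `pos_cM` is absent it can be derived from `pos_bp`
#' with a cM/Mb scalar (see [calibrate_cm_per_mb()]).
#'
#' @param name marker names (unique).
#' @param chrom chromosome per marker.
#' @param pos_bp 1-based physical positions (>= 1).
#' @param pos_cM optional genetic positions.
#' @param map_function `"kosambi"` or `"haldane"`, stored as an attribute and
#'   used by everything that converts cM distances to recombination fractions.
#' @param cm_per_mb optional scalar used to fill in `pos_cM` from `pos_bp`
#'   (per chromosome, anchored at the first marker) when `pos_cM` is missing.
#' @return a `data.frame` of class `marker_map`.
#' @export
marker_map <- function(name, chrom, pos_bp, pos_cM = NULL,
                       map_function = c("kosambi", "haldane"),
                       cm_per_mb = NULL) {
  map_function <- match.arg(map_function)
  name <- as.character(name); chrom <- as.character(chrom)
  pos_bp <- as.numeric(pos_bp)
  assert_that(!anyDuplicated(name), "marker names must be unique")
  assert_that(all(pos_bp >= 1), "pos_bp must be >= 1")
  m <- data.frame(name = name, chrom = chrom, pos_bp = pos_bp,
                  stringsAsFactors = FALSE)
  if (!is.null(pos_cM)) m$pos_cM <- as.numeric(pos_cM)
  m <- m[order(factor(m$chrom, levels = unique(m$chrom)), m$pos_bp), ,
         drop = FALSE]
  rownames(m) <- NULL
  for (ch in unique(m$chrom)) {
    i <- m$chrom == ch
    assert_that(!anyDuplicated(m$pos_bp[i]),
                "markers on chromosome %s must have distinct pos_bp", ch)
    if (!is.null(m$pos_cM))
      assert_that(!is.unsorted(m$pos_cM[i]),
                  "pos_cM must be non-decreasing with pos_bp on chromosome %s", ch)
  }
  if (is.null(m$pos_cM) && !is.null(cm_per_mb)) {
    m$pos_cM <- NA_real_
    for (ch in unique(m$chrom)) {
      i <- m$chrom == ch
      m$pos_cM[i] <- (m$pos_bp[i] - min(m$pos_bp[i])) / 1e6 * cm_per_mb
    }
  }
  structure(m, class = c("marker_map", "data.frame"),
            map_function = map_function)
}

map_function_of <- function(map) attr(map, "map_function") %||% "kosambi"

#' Read / write a marker map as TSV
#'
#' Columns: `name`, `chrom`, `pos_bp` and optionally `pos_cM`.
#'
#' @param path file path.
#' @param map a [marker_map()].
#' @inheritParams marker_map
#' @return `read_marker_map()` returns a `marker_map`;
#'   `write_marker_map()` returns `path` invisibly.
#' @rdname marker_map_io
#' @export
read_marker_map <- function(path, map_function = c("kosambi", "haldane")) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("name", "chrom", "pos_bp") %in% names(d)),
              "marker map TSV needs columns name, chrom, pos_bp")
  marker_map(d$name, d$chrom, d$pos_bp, pos_cM = d$pos_cM,
             map_function = match.arg(map_function))
}

#' @rdname marker_map_io
#' @export
write_marker_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @importFrom utils write.table
NULL

# per-chromosome cM positions; requires pos_cM
chrom_cM <- function(map, chrom) {
  i <- map$chrom == chrom
  assert_that(any(i), "chromosome %s not in map", chrom)
  assert_that(!is.null(map$pos_cM), "map has no pos_cM (supply cm_per_mb)")
  map$pos_cM[i]
}
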