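GENO_CODES <- c("A", "H", "B")

#' Construct a genotype matrix
#'
#' Lines x ordered markers with calls in `A` (parent-1 homozygote), `H`
#' (heterozygote), `B` (parent-2 homozygote) or `NA` (missing, written `-`
#' on disk). The marker map travels with the matrix.
#'
#' @param calls character matrix (lines in rows, markers in columns) with
#'   values in `A/H/B` or `NA`.
#' @param line_ids unique line identifiers (defaults to rownames).
#' @param map a [marker_map()] whose marker names match `colnames(calls)`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, line_ids = rownames(calls), map) {
  calls <- as.matrix(calls)
  assert_that(!is.null(line_ids) && !anyDuplicated(line_ids),
              "line ids must be present and unique")
  assert_that(inherits(map, "marker_map"), "map must be a marker_map")
  assert_that(identical(colnames(calls), map$name),
              "colnames(calls) must equal map marker names (same order)")
  bad <- !is.na(calls) & !(calls %in% GENO_CODES)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop_bad("invalid genotype code '%s' for line '%s', marker '%s'",
             calls[w[1], w[2]], line_ids[w[1]], colnames(calls)[w[2]])
  }
  rownames(calls) <- line_ids
  structure(list(calls = calls, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d lines x %d markers (%s), %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls),
              paste(unique(x$map$chrom), collapse = ","),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

line_ids <- function(gm) rownames(gm$calls)

#' Per-marker missing fraction
#' @param gm a [genotype_matrix()].
#' @return named numeric vector.
#' @export
missing_fraction <- function(gm) colMeans(is.na(gm$calls))

#' Read / write genotype matrices as CSV
#'
#' On-disk layout: first column `line_id`, remaining columns named by marker,
#' cells in `A/H/B/-`. `read_genotype_csv()` validates cells and reports the
#' offending line and marker for unknown symbols; duplicated line ids and
#' ragged rows are errors. Writing then reading returns an identical object.
#'
#' @param path CSV path.
#' @param map a [marker_map()] covering the file's marker columns.
#' @param gm a [genotype_matrix()].
#' @return `read_genotype_csv()` a `genotype_matrix`; `write_genotype_csv()`
#'   `path`, invisibly.
#' @rdname genotype_csv
#' @export
read_genotype_csv <- function(path, map) {
  nf <- count.fields(path, sep = ",", quote = "\"")
  assert_that(length(nf) >= 2, "genotype CSV '%s' has no data rows", path)
  assert_that(length(unique(nf)) == 1,
              "ragged genotype CSV '%s': rows have %s fields", path,
              paste(unique(nf), collapse = "/"))
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                colClasses = "character")
  assert_that(names(d)[1] == "line_id", "first column must be line_id")
  ids <- d[[1]]
  assert_that(!anyDuplicated(ids), "duplicate line_id in '%s': %s", path,
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(d[, -1, drop = FALSE])
  bad <- !(m %in% c(GENO_CODES, "-", ""))
  if (any(bad)) {
    w <- which(matrix(bad, nrow(m)), arr.ind = TRUE)[1, ]
    stop_bad("invalid genotype code '%s' at line '%s', marker '%s' in '%s'",
             m[w[1], w[2]], ids[w[1]], colnames(m)[w[2]], path)
  }
  m[m %in% c("-", "")] <- NA_character_
  keep <- map$name[map$name %in% colnames(m)]
  assert_that(length(keep) == ncol(m),
              "markers in '%s' missing from map: %s", path,
              paste(setdiff(colnames(m), map$name), collapse = ", "))
  submap <- map[map$name %in% keep, , drop = FALSE]
  class(submap) <- class(map); attr(submap, "map_function") <- map_function_of(map)
  genotype_matrix(m[, submap$name, drop = FALSE], ids, submap)
}

#' @rdname genotype_csv
#' @export
write_genotype_csv <- function(gm, path) {
  m <- gm$calls
  m[is.na(m)] <- "-"
  d <- data.frame(line_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a noisy marker assay
#'
#' Masks each call independently with probability `missing_rate` and corrupts
#' each (pre-masking) call with probability `error_rate`, replacing it by one
#' of the two other visible codes uniformly (so the expected mismatch rate
#' against truth among non-missing calls is exactly `error_rate`).
#'
#' @param gm a [genotype_matrix()] of true genotypes.
#' @param missing_rate,error_rate rates in `[0, 1)`.
#' @return a new `genotype_matrix`.
#' @export
simulate_marker_assay <- function(gm, missing_rate = 0, error_rate = 0) {
  assert_that(missing_rate >= 0 && missing_rate < 1 &&
              error_rate >= 0 && error_rate < 1, "rates must be in [0,1)")
  m <- gm$calls
  n <- length(m)
  if (error_rate > 0) {
    flip <- !is.na(m) & runif(n) < error_rate
    if (any(flip)) {
      cur <- m[flip]
      # uniform among the two wrong codes
      pick <- ifelse(runif(sum(flip)) < 0.5, 1L, 2L)
      wrong <- t(vapply(cur, function(cc) setdiff(GENO_CODES, cc), character(2)))
      m[flip] <- wrong[cbind(seq_along(cur), pick)]
    }
  }
  if (missing_rate > 0) m[runif(n) < missing_rate] <- NA_character_
  genotype_matrix(m, rownames(gm$calls), gm$map)
}
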