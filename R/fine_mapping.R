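#' Find recombinants between two flanking markers
#'
#' A line is recombinant when its calls at the two flanks are both
#' non-missing and differ (any of A/H, H/B, A/B); lines missing either flank
#' are excluded and reported separately. Swapped flanks are auto-corrected
#' with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param left_marker,right_marker flanking marker names (left = smaller bp).
#' @return list with `recombinant`, `non_recombinant`, `missing` line-id
#'   vectors and the screened `fraction` (recombinant / scored).
#' @export
find_recombinants <- function(gm, left_marker, right_marker) {
  map <- gm$map
  assert_that(all(c(left_marker, right_marker) %in% map$name),
              "both flanking markers must be present")
  pl <- map$pos_bp[map$name == left_marker]
  pr <- map$pos_bp[map$name == right_marker]
  if (pl > pr) {
    warning("flanking markers given in reverse order; swapping")
    tmp <- left_marker; left_marker <- right_marker; right_marker <- tmp
  }
  a <- gm$calls[, left_marker]
  b <- gm$calls[, right_marker]
  miss <- is.na(a) | is.na(b)
  rec <- !miss & a != b
  list(recombinant = line_ids(gm)[rec],
       non_recombinant = line_ids(gm)[!miss & !rec],
       missing = line_ids(gm)[miss],
       fraction = sum(rec) / sum(!miss))
}

#' Group recombinant lines into breakpoint classes
#'
#' Two lines share a class when their genotype code vectors over the region
#' markers are identical under missing-tolerant matching (missing agrees with
#' anything). Lines with more than half of the region missing are flagged
#' unclassifiable. Complete (no-missing) patterns seed the classes; lines
#' with missing calls join the unique compatible class, or are flagged
#' ambiguous when several classes fit.
#'
#' @param gm a [genotype_matrix()].
#' @param region_markers ordered marker names delimiting the region.
#' @param line_subset optional line ids to classify (default all).
#' @return list with `classes` (list of line-id vectors keyed by class
#'   pattern), `unclassifiable`, `ambiguous`.
#' @export
group_by_breakpoint <- function(gm, region_markers, line_subset = NULL) {
  assert_that(all(region_markers %in% gm$map$name),
              "region markers must be on the map")
  m <- gm$calls[, region_markers, drop = FALSE]
  if (!is.null(line_subset)) m <- m[line_subset, , drop = FALSE]
  frac_missing <- rowMeans(is.na(m))
  unclass_ids <- rownames(m)[frac_missing > 0.5]
  work <- m[frac_missing <= 0.5, , drop = FALSE]
  complete <- !apply(is.na(work), 1, any)
  pats <- apply(work, 1, paste, collapse = "")
  seeds <- unique(pats[complete])
  seed_mat <- do.call(rbind, strsplit(seeds, ""))
  classes <- lapply(seeds, function(s) rownames(work)[complete & pats == s])
  names(classes) <- seeds
  ambiguous <- character(0)
  for (id in rownames(work)[!complete]) {
    v <- work[id, ]
    if (is.null(seed_mat)) { compat <- integer(0) } else {
      ok <- apply(seed_mat, 1, function(s) {
        nz <- !is.na(v); all(s[nz] == v[nz])
      })
      compat <- which(ok)
    }
    if (length(compat) == 1) {
      classes[[compat]] <- c(classes[[compat]], id)
    } else if (length(compat) == 0) {
      key <- paste(ifelse(is.na(v), "-", v), collapse = "")
      classes[[key]] <- c(classes[[key]] %||% character(0), id)
      if (!is.null(seed_mat)) seed_mat <- rbind(seed_mat, ifelse(is.na(v), NA, v))
      else seed_mat <- rbind(ifelse(is.na(v), NA, v))
    } else {
      ambiguous <- c(ambiguous, id)
    }
  }
  list(classes = classes, unclassifiable = unclass_ids, ambiguous = ambiguous)
}

#' Heterozygous-segment bounds of a recombinant family founder
#'
#' The minimal heterozygous segment spans the outermost `H` calls
#' (inclusive); the maximal segment is marker-bounded by the nearest
#' flanking non-H, non-missing markers (the locus, if segregating in this
#' family, lies in its open interior). When no bounding marker exists on a
#' side, the region edge is used.
#'
#' @param calls named genotype code vector over the ordered region markers.
#' @param map a [marker_map()] covering those markers.
#' @param chrom chromosome (defaults to the single chromosome present).
#' @return list with `min` and `max` [genomic_interval()]s (both `NULL` when
#'   there is no `H` call).
#' @export
het_segments <- function(calls, map, chrom = NULL) {
  mk <- names(calls)
  assert_that(!is.null(mk) && all(mk %in% map$name),
              "calls must be named by mapped markers")
  pos <- map$pos_bp[match(mk, map$name)]
  chrom <- chrom %||% unique(map$chrom[match(mk, map$name)])
  assert_that(length(chrom) == 1, "region spans several chromosomes")
  o <- order(pos)
  calls <- calls[o]; pos <- pos[o]
  h <- which(calls == "H")
  if (length(h) == 0) return(list(min = NULL, max = NULL))
  seg_min <- genomic_interval(chrom, pos[min(h)], pos[max(h)])
  left <- which(!is.na(calls) & calls != "H" & seq_along(calls) < min(h))
  right <- which(!is.na(calls) & calls != "H" & seq_along(calls) > max(h))
  lo <- if (length(left)) pos[max(left)] else pos[1]
  hi <- if (length(right)) pos[min(right)] else pos[length(pos)]
  list(min = seg_min, max = genomic_interval(chrom, lo, hi))
}

#' Recombinant family record
#'
#' Bundles a family's founder genotype over the region markers with its
#' heterozygous-segment bounds.
#'
#' @param family_id identifier.
#' @param calls named founder genotype vector over the region markers.
#' @param map a [marker_map()].
#' @return object of class `recombinant_family`.
#' @export
recombinant_family <- function(family_id, calls, map) {
  seg <- het_segments(calls, map)
  structure(list(family_id = family_id, calls = calls,
                 het_min = seg$min, het_max = seg$max),
            class = "recombinant_family")
}

#' Classify a progeny test
#'
#' Combined ANOVA of the two homozygous sister-line classes across
#' experiments (experiments as blocks, via [blocked_ls_means()]): a
#' significant class effect (`P < alpha`) means the locus segregates in the
#' family, i.e. lies in the founder's heterozygous region
#' (classification `"heterozygous"`); otherwise `"homozygous"`.
#'
#' @param records data.frame with columns `class` (two homozygous sister-line
#'   classes), `experiment`, `value`.
#' @param alpha two-sided significance level (default 0.05).
#' @return object of class `progeny_test`: list with `classification`, `F`,
#'   `p`, `alpha`, `means`.
#' @export
progeny_test_classify <- function(records, alpha = 0.05) {
  cls <- unique(records$class[!is.na(records$class)])
  assert_that(length(cls) == 2,
              "progeny test incomplete: need exactly two sister-line classes")
  an <- blocked_ls_means(records, response = "value", level = "class",
                         block = "experiment")
  structure(list(classification = if (an$p < alpha) "heterozygous" else "homozygous",
                 F = an$F, p = an$p, alpha = alpha, means = an$means),
            class = "progeny_test")
}

#' Deduce the locus interval from classified recombinant families
#'
#' Heterozygous-classified families constrain the locus to the open interior
#' of their maximal heterozygous segments; homozygous-classified families
#' exclude their minimal heterozygous segments. The candidate interval is the
#' intersection of the heterozygous constraints minus the union of the
#' homozygous exclusions, reported as the largest remaining marker-bounded
#' interval. Families that would empty the result are removed greedily (the
#' removal restoring the most width first) and reported as conflicts, never
#' silently dropped.
#'
#' @param families list of entries, each a list with `family` (a
#'   [recombinant_family()]) and `classification` (`"heterozygous"` /
#'   `"homozygous"`, e.g. from [progeny_test_classify()]).
#' @return object of class `locus_deduction`: list with `candidate_interval`,
#'   `pieces` (all surviving sub-intervals), `conflicts` (family ids removed),
#'   `constraints` (per-family intervals used).
#' @export
deduce_locus_interval <- function(families) {
  info <- lapply(families, function(f) {
    cl <- f$classification %||% f$test$classification
    assert_that(cl %in% c("heterozygous", "homozygous"),
                "each family needs a heterozygous/homozygous classification")
    list(id = f$family$family_id, class = cl,
         het_max = f$family$het_max, het_min = f$family$het_min)
  })
  hets <- Filter(function(x) x$class == "heterozygous", info)
  homs <- Filter(function(x) x$class == "homozygous", info)
  assert_that(length(hets) >= 1, "need >= 1 heterozygous-classified family")
  conflicts <- character(0)
  repeat {
    cand <- intersect_intervals(lapply(hets, `[[`, "het_max"))
    if (!is.null(cand) && interval_width(cand) > 0) break
    assert_that(length(hets) > 1,
                "no candidate interval: heterozygous constraints are empty")
    # drop the het family whose removal restores the widest intersection
    widths <- vapply(seq_along(hets), function(i) {
      iv <- intersect_intervals(lapply(hets[-i], `[[`, "het_max"))
      if (is.null(iv)) -1 else interval_width(iv)
    }, numeric(1))
    drop_i <- which.max(widths)
    conflicts <- c(conflicts, hets[[drop_i]]$id)
    hets <- hets[-drop_i]
  }
  pieces <- list(cand)
  used_homs <- list()
  for (hm in homs) {
    if (is.null(hm$het_min)) next
    new_pieces <- unlist(lapply(pieces, interval_subtract, excl = hm$het_min),
                         recursive = FALSE)
    new_pieces <- Filter(function(iv) interval_width(iv) > 0, new_pieces)
    if (length(new_pieces) == 0) {
      conflicts <- c(conflicts, hm$id)  # exclusion would erase the locus
    } else {
      pieces <- new_pieces
      used_homs <- c(used_homs, list(hm))
    }
  }
  widths <- vapply(pieces, interval_width, numeric(1))
  structure(list(candidate_interval = pieces[[which.max(widths)]],
                 pieces = pieces, conflicts = conflicts,
                 constraints = info),
            class = "locus_deduction")
}

#' @export
print.locus_deduction <- function(x, ...) {
  cat("Locus deduction\n  candidate: ")
  print(x$candidate_interval)
  if (length(x$conflicts))
    cat("  conflicts:", paste(x$conflicts, collapse = ", "), "\n")
  invisible(x)
}

#' Plan the next screening phase
#'
#' Given the expected recombinant fraction inside the current interval
#' (from the cM/Mb calibration and screen type), the number of plants needed
#' to expect `target` new recombinants is `N = ceiling(target / p)`; the
#' probability of seeing none in `N` plants is `(1 - p)^N`.
#'
#' @param interval current candidate [genomic_interval()].
#' @param cm_per_mb calibrated scalar (see [calibrate_cm_per_mb()]).
#' @param target desired number of new recombinants (> 0).
#' @param n_planned optionally, a plant count to evaluate instead of the
#'   derived `N` for the zero-recombinant probability.
#' @inheritParams expected_recombinant_fraction
#' @return list with `p_recombinant`, `n_required`, `p_zero`.
#' @export
plan_rescreen <- function(interval, cm_per_mb, target,
                          screen = c("F2_plants", "gametes"),
                          kind = c("kosambi", "haldane"), n_planned = NULL) {
  assert_that(target > 0, "target must be positive")
  p <- expected_recombinant_fraction(interval_width(interval), cm_per_mb,
                                     match.arg(screen), match.arg(kind))
  assert_that(p > 0, "expected recombinant fraction is zero")
  N <- ceiling(target / p)
  list(p_recombinant = p, n_required = N,
       p_zero = (1 - p)^(n_planned %||% N))
}
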