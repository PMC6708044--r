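f2_transition <- function(r) {
  matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
           r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
           r^2, 2 * r * (1 - r), (1 - r)^2),
         3, 3, byrow = TRUE, dimnames = list(GENO_CODES, GENO_CODES))
}

ril_transition <- function(R) {
  matrix(c(1 - R, R, R, 1 - R), 2, 2, byrow = TRUE,
         dimnames = list(c("A", "B"), c("A", "B")))
}

#' Conditional genotype probabilities along the genome
#'
#' For every line and evaluation position, the probability of each genotype
#' class given the nearest informative flanking marker calls, using the
#' map's mapping function to turn cM distances into recombination fractions.
#' F2 probabilities condition a three-state Markov chain (AA/AB/BB, the
#' two-gamete chain under no interference) on the flanks; selfed-RIL
#' probabilities use the two-state A/B chain with the expanded fraction
#' `R = 2r/(1+2r)`, and heterozygous RIL calls are treated as missing (the
#' locus is still segregating there) and flagged. A non-missing typed marker
#' gets a point mass on the observed call. Lines with no informative call on
#' a chromosome fall back to the population prior and are flagged.
#'
#' @param gm a [genotype_matrix()] whose map has `pos_cM`.
#' @param pop_type `"F2"` or `"RIL_self"`.
#' @param step pseudo-position spacing in cM (`NULL` = markers only).
#' @return an object of class `geno_probs`: list with `positions`
#'   (data.frame chrom, pos_cM, pos_bp, marker), `prob` (lines x positions x
#'   A/H/B array), `dosage` (expected additive dosage, A = -1, B = +1),
#'   `dom` (P(H)), `pop_type`, `flagged`.
#' @export
conditional_genotype_probs <- function(gm, pop_type = c("F2", "RIL_self"),
                                       step = NULL) {
  pop_type <- match.arg(pop_type)
  map <- gm$map
  kind <- map_function_of(map)
  assert_that(!is.null(map$pos_cM), "map needs pos_cM")
  pos <- scan_positions(map, step)
  n <- nrow(gm$calls)
  P <- nrow(pos)
  prob <- array(0, c(n, P, 3),
                dimnames = list(line_ids(gm), NULL, GENO_CODES))
  prior <- if (pop_type == "F2") c(.25, .5, .25) else c(.5, 0, .5)
  flagged <- character(0)
  for (ch in unique(map$chrom)) {
    midx <- which(map$chrom == ch)
    pidx <- which(pos$chrom == ch)
    mcm <- map$pos_cM[midx]
    ecm <- pos$pos_cM[pidx]
    obs <- gm$calls[, midx, drop = FALSE]
    if (pop_type == "RIL_self") obs[obs == "H"] <- NA_character_
    if (!anyNA(obs) && length(pidx) == length(midx) &&
        isTRUE(all(ecm == mcm))) {
      # complete data evaluated at the typed markers: point masses
      ii <- rep(seq_len(n), times = length(midx))
      jj <- rep(pidx, each = n)
      kk <- match(as.vector(obs), GENO_CODES)
      prob[cbind(ii, jj, kk)] <- 1
      next
    }
    for (i in seq_len(n)) {
      inf <- which(!is.na(obs[i, ]))
      if (length(inf) == 0) {
        flagged <- union(flagged, line_ids(gm)[i])
        prob[i, pidx, ] <- matrix(prior, length(pidx), 3, byrow = TRUE)
        next
      }
      icm <- mcm[inf]
      li <- findInterval(ecm, icm)
      for (jj in seq_along(pidx)) {
        L <- li[jj]; R <- L + 1L
        atL <- L >= 1 && ecm[jj] == icm[L]
        if (atL) {
          prob[i, pidx[jj], obs[i, inf[L]]] <- 1
          next
        }
        gL <- if (L >= 1) obs[i, inf[L]] else NA
        gR <- if (R <= length(inf)) obs[i, inf[R]] else NA
        rL <- if (!is.na(gL)) map_recfrac(ecm[jj] - icm[L], kind) else NA
        rR <- if (!is.na(gR)) map_recfrac(icm[R] - ecm[jj], kind) else NA
        prob[i, pidx[jj], ] <- flank_probs(gL, gR, rL, rR, pop_type, prior)
      }
    }
  }
  dosage <- prob[, , "B", drop = FALSE] - prob[, , "A", drop = FALSE]
  dim(dosage) <- c(n, P)
  dom <- prob[, , "H", drop = FALSE]
  dim(dom) <- c(n, P)
  structure(list(positions = pos, prob = prob, dosage = dosage, dom = dom,
                 pop_type = pop_type, lines = line_ids(gm), flagged = flagged),
            class = "geno_probs")
}

flank_probs <- function(gL, gR, rL, rR, pop_type, prior) {
  if (pop_type == "F2") {
    w <- prior
    if (!is.na(gL)) w <- f2_transition(rL)[gL, ]
    if (!is.na(gR)) w <- w * f2_transition(rR)[, gR]
    return(w / sum(w))
  }
  # RIL: two-state chain with expanded recombination
  w2 <- c(.5, .5)
  if (!is.na(gL)) w2 <- ril_transition(ril_expansion(rL))[gL, ]
  if (!is.na(gR)) w2 <- w2 * ril_transition(ril_expansion(rR))[, gR]
  w2 <- w2 / sum(w2)
  c(w2[1], 0, w2[2])
}

scan_positions <- function(map, step = NULL) {
  out <- data.frame(chrom = map$chrom, pos_cM = map$pos_cM,
                    pos_bp = map$pos_bp, marker = map$name,
                    stringsAsFactors = FALSE)
  if (!is.null(step)) {
    for (ch in unique(map$chrom)) {
      i <- which(map$chrom == ch)
      grid <- seq(min(map$pos_cM[i]), max(map$pos_cM[i]), by = step)
      grid <- setdiff(round(grid, 9), round(map$pos_cM[i], 9))
      if (length(grid)) {
        bp <- stats::approx(map$pos_cM[i], map$pos_bp[i], xout = grid,
                            ties = "ordered")$y
        out <- rbind(out, data.frame(chrom = ch, pos_cM = grid, pos_bp = bp,
                                     marker = NA_character_,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[order(factor(out$chrom, levels = unique(map$chrom)),
                   out$pos_cM, out$pos_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Haley-Knott genome scan
#'
#' At each evaluation position the phenotype is regressed on the expected
#' additive dosage (plus the expected dominance indicator for F2), and
#' `LOD = (n/2) log10(RSS0 / RSS1)` compares the fit against the
#' intercept-only model. The percent of variance explained satisfies
#' `pve = 1 - 10^(-2 LOD / n)` identically. With a complete non-missing
#' marker this reduces exactly to single-marker regression, and the LOD is
#' invariant to affine transformations of the phenotype.
#'
#' @param probs a [conditional_genotype_probs()] result.
#' @param phenotype named numeric vector of line values (e.g. environment
#'   -adjusted means); names matched against the genotyped lines.
#' @return a `lod_curve` data.frame: chrom, pos_cM, pos_bp, marker, LOD,
#'   effect (additive coefficient), pve; attribute `n`.
#' @export
hk_scan <- function(probs, phenotype) {
  keep <- probs$lines[probs$lines %in% names(phenotype)]
  keep <- keep[!is.na(phenotype[keep])]
  assert_that(length(keep) >= 3, "need >= 3 phenotyped lines")
  y <- as.numeric(phenotype[keep])
  li <- match(keep, probs$lines)
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  P <- nrow(probs$positions)
  LOD <- effect <- numeric(P)
  if (rss0 == 0) {
    warning("zero phenotypic variance; LOD curve is identically 0")
  } else {
    use_dom <- probs$pop_type == "F2"
    for (p in seq_len(P)) {
      x <- probs$dosage[li, p]
      X <- cbind(1, x)
      if (use_dom) X <- cbind(X, probs$dom[li, p])
      keepcol <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(cc) sd(cc) > 0))
      X <- X[, keepcol, drop = FALSE]
      if (ncol(X) == 1) { LOD[p] <- 0; effect[p] <- 0; next }
      fit <- stats::lm.fit(X, y)
      rss1 <- sum(fit$residuals^2)
      LOD[p] <- (n / 2) * log10(rss0 / rss1)
      effect[p] <- if (keepcol[2]) fit$coefficients[2] else 0
    }
  }
  out <- probs$positions
  out$LOD <- pmax(0, LOD)
  out$effect <- effect
  out$pve <- 1 - 10^(-2 * out$LOD / n)
  attr(out, "n") <- n
  class(out) <- c("lod_curve", "data.frame")
  out
}

#' Peaks of a LOD curve
#'
#' One peak per chromosome: the maximum-LOD position (ties broken toward the
#' smaller bp coordinate) when it clears the threshold, with a LOD-drop
#' support interval (the contiguous run around the peak whose LOD stays
#' within `drop` of the peak).
#'
#' @param curve a [hk_scan()] result.
#' @param threshold LOD significance threshold (default 2.0).
#' @param drop LOD drop for the support interval (default 1.5).
#' @return data.frame of peaks with support bounds in bp and cM.
#' @export
find_peaks <- function(curve, threshold = 2.0, drop = 1.5) {
  out <- NULL
  for (ch in unique(curve$chrom)) {
    d <- curve[curve$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos_bp), , drop = FALSE]
    i <- which.max(d$LOD)  # first max = smaller bp on ties
    if (d$LOD[i] < threshold) next
    lo <- i; while (lo > 1 && d$LOD[lo - 1] >= d$LOD[i] - drop) lo <- lo - 1
    hi <- i; while (hi < nrow(d) && d$LOD[hi + 1] >= d$LOD[i] - drop) hi <- hi + 1
    out <- rbind(out, data.frame(
      chrom = ch, pos_cM = d$pos_cM[i], pos_bp = d$pos_bp[i],
      marker = d$marker[i], LOD = d$LOD[i], effect = d$effect[i],
      pve = d$pve[i], support_lo_bp = d$pos_bp[lo], support_hi_bp = d$pos_bp[hi],
      support_lo_cM = d$pos_cM[lo], support_hi_cM = d$pos_cM[hi],
      stringsAsFactors = FALSE))
  }
  out %||% data.frame()
}

#' Joint multi-QTL fit with drop-one effects
#'
#' Additive linear model on the expected dosages at the given peak
#' positions (no interaction terms). Each QTL's percent variance explained
#' comes from the drop-one residual-sum-of-squares comparison:
#' `pve_q = (RSS_without_q - RSS_full) / TSS`.
#'
#' @param probs a [conditional_genotype_probs()] result.
#' @param phenotype named numeric vector of line values.
#' @param peaks data.frame with columns `chrom` and `pos_bp` (e.g. from
#'   [find_peaks()]); duplicated positions are rejected.
#' @return list with `qtl` (data.frame chrom, pos_bp, effect, pve, F, p),
#'   `total_pve`, `n`.
#' @export
multi_qtl_fit <- function(probs, phenotype, peaks) {
  assert_that(nrow(peaks) >= 1, "need >= 1 peak")
  key <- paste(peaks$chrom, peaks$pos_bp)
  assert_that(!anyDuplicated(key), "collinear peaks: duplicated positions")
  idx <- vapply(seq_len(nrow(peaks)), function(q) {
    j <- which(probs$positions$chrom == peaks$chrom[q] &
               probs$positions$pos_bp == peaks$pos_bp[q])
    assert_that(length(j) >= 1, "peak %s not among scan positions", key[q])
    j[1]
  }, integer(1))
  keep <- probs$lines[probs$lines %in% names(phenotype)]
  keep <- keep[!is.na(phenotype[keep])]
  y <- as.numeric(phenotype[keep])
  li <- match(keep, probs$lines)
  n <- length(y)
  X <- probs$dosage[li, idx, drop = FALSE]
  tss <- sum((y - mean(y))^2)
  full <- stats::lm.fit(cbind(1, X), y)
  rss_full <- sum(full$residuals^2)
  k <- ncol(X)
  pve <- Fst <- pv <- numeric(k)
  for (q in seq_len(k)) {
    red <- stats::lm.fit(cbind(1, X[, -q, drop = FALSE]), y)
    rss_red <- sum(red$residuals^2)
    pve[q] <- (rss_red - rss_full) / tss
    df2 <- n - (k + 1)
    Fst[q] <- (rss_red - rss_full) / (rss_full / df2)
    pv[q] <- pf(Fst[q], 1, df2, lower.tail = FALSE)
  }
  list(qtl = data.frame(chrom = peaks$chrom, pos_bp = peaks$pos_bp,
                        effect = full$coefficients[-1], pve = pve,
                        F = Fst, p = pv, stringsAsFactors = FALSE),
       total_pve = 1 - rss_full / tss, n = n)
}
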