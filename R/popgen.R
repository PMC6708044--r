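#' Allele / haplotype frequency table by group
#'
#' Counts and half-up one-decimal percentages per group. Unclassified calls
#' (by default `ancestral_unresolved` kept, `inconsistent` and `NA` dropped —
#' set `exclude` to control this) are reported separately and excluded from
#' the denominators.
#'
#' @param calls data.frame with columns `group` and `allele` (or a named
#'   list of count vectors).
#' @param exclude allele labels excluded from denominators.
#' @return data.frame with columns `group`, `allele`, `count`, `total`,
#'   `percent`; attribute `excluded` holds the per-group excluded counts.
#' @export
frequency_table <- function(calls, exclude = c("inconsistent")) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- do.call(rbind, lapply(names(calls), function(g)
      data.frame(group = g,
                 allele = rep(names(calls[[g]]), calls[[g]]),
                 stringsAsFactors = FALSE)))
  }
  keep <- !is.na(calls$allele) & !(calls$allele %in% exclude)
  excluded <- table(calls$group[!keep])
  d <- calls[keep, , drop = FALSE]
  empties <- setdiff(unique(calls$group), unique(d$group))
  if (length(empties))
    warning("group(s) with no classifiable calls dropped: ",
            paste(empties, collapse = ", "))
  out <- NULL
  for (g in unique(d$group)) {
    tab <- table(d$allele[d$group == g])
    out <- rbind(out, data.frame(group = g, allele = names(tab),
                                 count = as.integer(tab),
                                 total = sum(tab),
                                 percent = round_half_up(100 * as.integer(tab) / sum(tab), 1),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Pearson homogeneity chi-square test
#'
#' Tests whether allele proportions are homogeneous across groups:
#' `chi2 = sum (O - E)^2 / E` with `df = (r-1)(c-1)` and the p-value from
#' the upper chi-square tail. Cells with expected count below 5 are flagged
#' (the asymptotic approximation weakens there); zero row/column margins are
#' rejected.
#'
#' @param counts matrix of counts, groups x categories.
#' @return list with `chi2`, `df`, `p`, `expected`, `flagged` (logical
#'   matrix of low-expectation cells).
#' @export
chi2_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  assert_that(nrow(counts) >= 2 && ncol(counts) >= 2,
              "need >= 2 groups and >= 2 categories")
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  rs <- rowSums(counts); cs <- colSums(counts)
  assert_that(all(rs > 0) && all(cs > 0), "zero-margin row/column rejected")
  E <- outer(rs, cs) / sum(counts)
  chi2 <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       expected = E, flagged = E < 5)
}

#' Multi-environment effect table (LS means, differences, % differences)
#'
#' For each trait, the blocked ANOVA of [blocked_ls_means()] with
#' environments as blocks and the given line classification (marker or
#' haplotype group), plus the difference `comparison - baseline` and the
#' half-up one-decimal percent difference `100 * diff / baseline`.
#'
#' @param pheno phenotype table (`line_id, environment, replicate, trait,
#'   value`), possibly several traits.
#' @param classifier named character vector line_id -> level.
#' @param baseline,comparison level names for the difference rows (defaults:
#'   first and second level alphabetically).
#' @return data.frame with one row per trait: LS mean and SE per level,
#'   difference, percent difference, F, P.
#' @export
effect_table <- function(pheno, classifier, baseline = NULL, comparison = NULL) {
  pheno$level <- classifier[pheno$line_id]
  out <- NULL
  for (tr in unique(pheno$trait)) {
    d <- pheno[pheno$trait == tr & !is.na(pheno$level), , drop = FALSE]
    an <- blocked_ls_means(d, response = "value", level = "level",
                           block = "environment")
    lv <- an$means$level
    b <- baseline %||% lv[1]
    cmp <- comparison %||% lv[2]
    mb <- an$means$lsmean[an$means$level == b]
    mc <- an$means$lsmean[an$means$level == cmp]
    out <- rbind(out, data.frame(
      trait = tr, baseline = b, comparison = cmp,
      baseline_mean = mb, comparison_mean = mc,
      difference = mc - mb,
      percent_difference = percent_difference(mc - mb, mb),
      F = an$F, p = an$p, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Percent difference at printed precision
#'
#' `100 * difference / baseline`, rounded half-up to one decimal — the
#' convention of published effect tables.
#'
#' @param difference,baseline numeric.
#' @return percent, one decimal.
#' @examples
#' percent_difference(289.5, 4141)  # 7.0
#' percent_difference(90.8, 4350)   # 2.1
#' @export
percent_difference <- function(difference, baseline) {
  round_half_up(100 * difference / baseline, 1)
}

#' Relative transcript level as fold of the reference gene
#'
#' The 2^dCT quantification: `fold = 2^(CT_reference - CT_target)`, i.e. the
#' number of target molecules per reference (ACTIN) molecule. Monotone
#' decreasing in the target CT. PCR-efficiency correction is available but
#' off by default (plain 2^dCT is the standard report): with efficiency
#' `eff`, the base becomes `1 + eff`.
#'
#' @param ct_target,ct_actin cycle-threshold values (positive).
#' @param efficiency amplification efficiency in (0, 1]; default 1 (2^dCT).
#' @return fold-reference expression level.
#' @examples
#' fold_actin(25, 25)  # 1
#' fold_actin(26, 25)  # 0.5
#' @export
fold_actin <- function(ct_target, ct_actin, efficiency = 1) {
  assert_that(all(ct_target > 0) && all(ct_actin > 0), "CT values must be positive")
  (1 + efficiency)^(ct_actin - ct_target)
}

#' Compare expression between groups with Tukey letters
#'
#' Works on the log2 scale (the dCT differences), where the residuals are
#' closest to normal: one-way (optionally blocked) ANOVA of
#' `dCT = CT_reference - CT_target`, all-pairs Tukey HSD at `alpha`, and
#' compact letter display (groups sharing a letter do not differ
#' significantly).
#'
#' @param records data.frame with columns `group`, `ct_target`, `ct_actin`
#'   and optionally `block`.
#' @param alpha familywise significance level.
#' @return list with `means` (group, n, mean_fold, mean_dct, letters),
#'   `tukey` (the TukeyHSD table), `anova_p`.
#' @export
expression_comparison <- function(records, alpha = 0.05) {
  d <- data.frame(group = factor(records$group),
                  dct = records$ct_actin - records$ct_target)
  if (!is.null(records$block)) {
    d$block <- factor(records$block)
    fit <- aov(dct ~ block + group, data = d)
  } else {
    fit <- aov(dct ~ group, data = d)
  }
  tuk <- TukeyHSD(fit, which = "group", conf.level = 1 - alpha)$group
  an <- summary(fit)[[1]]
  p_group <- an[grep("^group", rownames(an)), "Pr(>F)"]
  groups <- levels(d$group)
  sig <- matrix(FALSE, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (k in seq_len(nrow(tuk))) {
    pair <- strsplit(rownames(tuk)[k], "-", fixed = TRUE)[[1]]
    s <- tuk[k, "p adj"] < alpha
    sig[pair[1], pair[2]] <- sig[pair[2], pair[1]] <- s
  }
  means <- vapply(groups, function(g) mean(d$dct[d$group == g]), numeric(1))
  letters <- compact_letters(sig, order(-means))
  list(means = data.frame(group = groups,
                          n = as.integer(table(d$group)[groups]),
                          mean_dct = means,
                          mean_fold = 2^means,
                          letters = letters,
                          stringsAsFactors = FALSE),
       tukey = tuk, anova_p = p_group)
}

# insert-and-absorb compact letter display; `ord` ranks groups (best first)
compact_letters <- function(sig, ord) {
  g <- nrow(sig)
  cols <- list(rep(TRUE, g))  # start with one letter containing everybody
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (j <= i || !sig[i, j]) next
    for (k in seq_along(cols)) {
      if (cols[[k]][i] && cols[[k]][j]) {
        # split column k: one without i, one without j
        c1 <- cols[[k]]; c1[i] <- FALSE
        c2 <- cols[[k]]; c2[j] <- FALSE
        cols[[k]] <- c1
        cols <- c(cols, list(c2))
      }
    }
    # absorb duplicated/contained columns
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] && all(cols[[a]] <= cols[[b]]))
        keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  lab <- rep("", g)
  cols <- cols[order(vapply(cols, function(cc) min(match(which(cc), ord)), numeric(1)))]
  for (k in seq_along(cols))
    lab[cols[[k]]] <- paste0(lab[cols[[k]]], letters[k])
  lab
}
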