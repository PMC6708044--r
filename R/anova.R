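#' Blocked ANOVA with least-squares means
#'
#' Fixed-effects two-way ANOVA `value ~ block + level` (no interaction), the
#' combined analysis used for multi-environment trials and progeny tests with
#' environments or experiments as blocks. The F test for `level` is the
#' extra-sum-of-squares test adjusted for blocks (equivalent to type III for
#' this additive model); least-squares means average the fitted cell means
#' over all blocks with equal weight, so with balanced data they equal the
#' raw level means.
#'
#' @param data data.frame of observations.
#' @param response,level,block column names of the numeric response, the
#'   classification factor and the block factor.
#' @return object of class `blocked_anova`: list with `means` (data.frame
#'   level, lsmean, se, n), `F`, `p`, `df1`, `df2`, `sigma`.
#' @export
blocked_ls_means <- function(data, response = "value", level = "level",
                             block = "environment") {
  d <- data.frame(y = data[[response]],
                  lv = factor(data[[level]]),
                  bl = factor(data[[block]]))
  d <- d[complete.cases(d), , drop = FALSE]
  assert_that(nlevels(droplevels(d$lv)) >= 2, "need >= 2 levels of '%s'", level)
  d$lv <- droplevels(d$lv); d$bl <- droplevels(d$bl)
  cnt <- table(d$lv)
  assert_that(all(cnt >= 2), "need >= 2 observations per level")
  fit_full <- lm(y ~ bl + lv, data = d)
  assert_that(!anyNA(coef(fit_full)),
              "design not connected: LS means not estimable")
  fit_red <- lm(y ~ bl, data = d)
  rss_full <- sum(fit_full$residuals^2)
  rss_red <- sum(fit_red$residuals^2)
  df1 <- fit_red$df.residual - fit_full$df.residual
  df2 <- fit_full$df.residual
  Fv <- if (rss_full == 0) Inf else ((rss_red - rss_full) / df1) / (rss_full / df2)
  pv <- pf(Fv, df1, df2, lower.tail = FALSE)
  # LS means: average model-matrix rows over the block grid per level
  V <- vcov(fit_full)
  beta <- coef(fit_full)
  lvs <- levels(d$lv)
  means <- data.frame(level = lvs, lsmean = NA_real_, se = NA_real_,
                      n = as.integer(cnt[lvs]), stringsAsFactors = FALSE)
  for (i in seq_along(lvs)) {
    grid <- data.frame(bl = factor(levels(d$bl), levels = levels(d$bl)),
                       lv = factor(lvs[i], levels = lvs))
    mm <- model.matrix(~ bl + lv, grid)
    cvec <- colMeans(mm)
    means$lsmean[i] <- sum(cvec * beta)
    means$se[i] <- sqrt(drop(t(cvec) %*% V %*% cvec))
  }
  structure(list(means = means, F = Fv, p = pv, df1 = df1, df2 = df2,
                 sigma = sqrt(rss_full / df2)),
            class = "blocked_anova")
}

#' @export
print.blocked_anova <- function(x, ...) {
  cat(sprintf("Blocked ANOVA: F(%d,%d) = %.3f, P = %.3g, pooled SD = %.3f\n",
              x$df1, x$df2, x$F, x$p, x$sigma))
  print(x$means, row.names = FALSE)
  invisible(x)
}
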