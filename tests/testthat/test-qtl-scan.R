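# exhaustive two-gamete enumeration of P(G_Q | G_L, G_R) for an F2 (oracle)
f2_enum_oracle <- function(r1, r2, gl, gr) {
  haps <- expand.grid(a1 = 0:1, a2 = 0:1, a3 = 0:1)
  hp <- apply(haps, 1, function(h) {
    0.5 * (if (h[1] != h[2]) r1 else 1 - r1) *
      (if (h[2] != h[3]) r2 else 1 - r2)
  })
  code <- function(s) c("A", "H", "B")[s + 1]
  joint <- array(0, c(3, 3, 3), dimnames = list(c("A","H","B"), c("A","H","B"),
                                                c("A","H","B")))
  for (i in seq_len(8)) for (j in seq_len(8)) {
    g <- unlist(haps[i, ]) + unlist(haps[j, ])
    joint[code(g[1]), code(g[2]), code(g[3])] <-
      joint[code(g[1]), code(g[2]), code(g[3])] + hp[i] * hp[j]
  }
  p <- joint[gl, , gr]
  p / sum(p)
}

test_that("F2 conditional probabilities match the two-gamete enumeration", {
  map <- marker_map(c("L", "Q", "R"), rep("1A", 3),
                    c(1e6, 4e6, 9e6), c(0, 7, 19), map_function = "haldane")
  r1 <- map_recfrac(7, "haldane"); r2 <- map_recfrac(12, "haldane")
  combos <- expand.grid(gl = c("A", "H", "B"), gr = c("A", "H", "B"),
                        stringsAsFactors = FALSE)
  calls <- cbind(combos$gl, NA_character_, combos$gr)
  colnames(calls) <- map$name
  gm <- genotype_matrix(calls, sprintf("L%d", 1:9), map)
  pr <- conditional_genotype_probs(gm, "F2")
  qpos <- which(pr$positions$marker == "Q")
  for (i in 1:9) {
    expect_lt(max(abs(pr$prob[i, qpos, ] -
                      f2_enum_oracle(r1, r2, combos$gl[i], combos$gr[i]))),
              1e-10)
  }
  # probabilities sum to one everywhere; observed markers get point mass
  expect_true(all(abs(apply(pr$prob, 1:2, sum) - 1) < 1e-9))
  expect_equal(unname(pr$prob[1, 1, ]), c(1, 0, 0))
})

test_that("RIL probabilities are symmetric at the midpoint of opposite flanks", {
  map <- marker_map(c("L", "M", "R"), rep("2B", 3), c(1e6, 2e6, 3e6),
                    c(0, 5, 10), map_function = "kosambi")
  gm <- gm_from_strings(c("A-B", "B-A"), map)
  pr <- conditional_genotype_probs(gm, "RIL_self")
  mpos <- which(pr$positions$marker == "M")
  for (i in 1:2) {
    expect_equal(unname(pr$prob[i, mpos, c("A", "B")]), c(0.5, 0.5))
    expect_equal(unname(pr$prob[i, mpos, "H"]), 0)
  }
  # a fully missing chromosome falls back to the prior and is flagged
  gm2 <- gm_from_strings(c("---", "AAB"), map)
  expect_equal(conditional_genotype_probs(gm2, "RIL_self")$flagged, "L01")
})

test_that("hk_scan holds the LOD/PVE identity and affine invariance", {
  set.seed(21)
  map <- tiny_map(n = 6, spacing_cM = 10)
  gm <- simulate_population(cross_design("RIL_self", 120, map, generation = 7))
  pr <- conditional_genotype_probs(gm, "RIL_self", step = 2)
  q <- data.frame(chrom = "1A", pos_bp = map$pos_bp[3], a = 1)
  ph <- simulate_phenotypes(gm, q, env_effects = c(E = 0), residual_sd = 1)
  y <- line_means(ph)
  sc <- hk_scan(pr, y)
  n <- attr(sc, "n")
  expect_equal(sc$pve, 1 - 10^(-2 * sc$LOD / n), tolerance = 1e-12)
  expect_true(all(sc$LOD >= 0))
  # affine transformation of the phenotype leaves the LOD curve unchanged
  sc2 <- hk_scan(pr, 3.7 * y - 11)
  expect_equal(sc2$LOD, sc$LOD, tolerance = 1e-9)
  expect_equal(sc2$effect, 3.7 * sc$effect, tolerance = 1e-9)
  # with complete (homozygous) genotypes at a marker, scanning there equals
  # plain marker regression: restrict to the lines typed A/B at marker 3
  ab <- rownames(gm$calls)[gm$calls[, 3] %in% c("A", "B")]
  ysub <- y[ab]
  scs <- hk_scan(pr, ysub)
  ns <- attr(scs, "n")
  j <- which(scs$marker == map$name[3])
  x <- ifelse(gm$calls[ab, 3] == "B", 1, -1)
  fit <- lm(ysub ~ x)
  rss0 <- sum((ysub - mean(ysub))^2); rss1 <- sum(residuals(fit)^2)
  expect_equal(scs$LOD[j], (ns / 2) * log10(rss0 / rss1), tolerance = 1e-9)
  expect_equal(scs$effect[j], unname(coef(fit)[2]), tolerance = 1e-9)
  # zero phenotypic variance: warning and flat curve
  expect_warning(sc0 <- hk_scan(pr, setNames(rep(2, length(y)), names(y))),
                 "zero")
  expect_true(all(sc0$LOD == 0))
})

test_that("a strong simulated QTL is localized within its 1.5-LOD support", {
  set.seed(22)
  map <- tiny_map(n = 11, spacing_cM = 10)
  hits <- 0L
  nsim <- 200
  for (s in seq_len(nsim)) {
    gm <- simulate_population(cross_design("RIL_self", 200, map, generation = 8))
    ph <- simulate_phenotypes(gm, data.frame(chrom = "1A", pos_bp = map$pos_bp[6],
                                             a = 1.05),
                              env_effects = c(E = 0), residual_sd = 1)
    pr <- conditional_genotype_probs(gm, "RIL_self")
    pk <- find_peaks(hk_scan(pr, line_means(ph)))
    if (nrow(pk) == 1 && pk$support_lo_bp <= map$pos_bp[6] &&
        pk$support_hi_bp >= map$pos_bp[6]) hits <- hits + 1L
  }
  expect_gte(hits / nsim, 0.95)
})

test_that("multi-QTL drop-one fit reduces, bounds and matches orthogonality", {
  set.seed(23)
  map <- multi_map(c("1A", "2B", "3D"), n = 5, spacing_cM = 20)
  gm <- simulate_population(cross_design("RIL_self", 150, map, generation = 8))
  qtls <- data.frame(chrom = c("1A", "2B", "3D"),
                     pos_bp = map$pos_bp[c(3, 8, 13)],
                     a = c(1, 0.7, 0.5))
  ph <- simulate_phenotypes(gm, qtls, env_effects = c(E = 0), residual_sd = 1)
  y <- line_means(ph)
  pr <- conditional_genotype_probs(gm, "RIL_self")
  # single peak: identical to the hk_scan fit at that position
  one <- multi_qtl_fit(pr, y, qtls[1, c("chrom", "pos_bp")])
  sc <- hk_scan(pr, y)
  j <- which(sc$chrom == "1A" & sc$pos_bp == qtls$pos_bp[1])
  expect_equal(one$qtl$pve, sc$pve[j], tolerance = 1e-9)
  expect_equal(one$qtl$effect, sc$effect[j], tolerance = 1e-9)
  # three QTLs: drop-one PVEs never exceed the joint model PVE
  fit3 <- multi_qtl_fit(pr, y, qtls[, c("chrom", "pos_bp")])
  expect_lte(sum(fit3$qtl$pve), fit3$total_pve + 1e-9)
  expect_error(multi_qtl_fit(pr, y, qtls[c(1, 1), ]), "collinear")
  # orthogonal designed genotypes: drop-one PVE equals marginal PVE exactly
  omap <- multi_map(c("1A", "2B"), n = 1)
  x1 <- rep(c("A", "B"), each = 8)
  x2 <- rep(rep(c("A", "B"), each = 4), 2)
  ogm <- genotype_matrix(cbind(`1A_m01` = x1, `2B_m01` = x2),
                         sprintf("O%02d", 1:16), omap)
  opr <- conditional_genotype_probs(ogm, "RIL_self")
  yo <- setNames(ifelse(x1 == "B", 1, -1) * 2 + ifelse(x2 == "B", 1, -1) +
                   rnorm(16, 0, 0.3), sprintf("O%02d", 1:16))
  both <- multi_qtl_fit(opr, yo, data.frame(chrom = c("1A", "2B"),
                                            pos_bp = omap$pos_bp))
  m1 <- multi_qtl_fit(opr, yo, data.frame(chrom = "1A", pos_bp = omap$pos_bp[1]))
  m2 <- multi_qtl_fit(opr, yo, data.frame(chrom = "2B", pos_bp = omap$pos_bp[2]))
  expect_equal(both$qtl$pve, c(m1$qtl$pve, m2$qtl$pve), tolerance = 1e-9)
})

test_that("blocked LS means match raw means when balanced and the
           normal-equations oracle when unbalanced", {
  set.seed(24)
  # balanced, no block effect: LS means equal raw level means
  d <- expand.grid(level = c("H1", "H2"), environment = c("E1", "E2"),
                   rep = 1:6, stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d)) + ifelse(d$level == "H2", 1, 0)
  an <- blocked_ls_means(d)
  raw <- tapply(d$value, d$level, mean)
  expect_equal(an$means$lsmean, as.numeric(raw[an$means$level]), tolerance = 1e-12)
  # unbalanced two-environment data: brute-force normal equations
  d2 <- d[-c(1, 2, 5), ]
  an2 <- blocked_ls_means(d2)
  X <- cbind(1, d2$environment == "E2", d2$level == "H2")
  beta <- solve(t(X) %*% X, t(X) %*% d2$value)
  rss_full <- sum((d2$value - X %*% beta)^2)
  X0 <- X[, 1:2]
  b0 <- solve(t(X0) %*% X0, t(X0) %*% d2$value)
  rss_red <- sum((d2$value - X0 %*% b0)^2)
  df2 <- nrow(d2) - 3
  F_oracle <- (rss_red - rss_full) / (rss_full / df2)
  expect_equal(an2$F, F_oracle, tolerance = 1e-9)
  expect_equal(an2$p, pf(F_oracle, 1, df2, lower.tail = FALSE), tolerance = 1e-9)
  # LS mean oracle: intercept + mean block effect (+ level effect)
  ls_H1 <- beta[1] + 0.5 * beta[2]
  ls_H2 <- beta[1] + 0.5 * beta[2] + beta[3]
  expect_equal(an2$means$lsmean, c(ls_H1, ls_H2), tolerance = 1e-9)
  # independent package cross-check
  if (requireNamespace("emmeans", quietly = TRUE)) {
    fit <- lm(value ~ factor(environment) + factor(level), data = d2)
    em <- as.data.frame(emmeans::emmeans(fit, "level"))
    expect_equal(an2$means$lsmean, em$emmean, tolerance = 1e-9)
    expect_equal(an2$means$se, em$SE, tolerance = 1e-9)
  }
  expect_error(blocked_ls_means(d[d$level == "H1", ]), ">= 2 levels")
})

test_that("the simulated RIL haplotype contrast recovers the 2.1-spikelet gap", {
  set.seed(25)
  map <- tiny_map(n = 3, spacing_cM = 30)
  ok <- 0L
  nsim <- 100
  for (s in seq_len(nsim)) {
    gm <- simulate_population(cross_design("RIL_self", 75, map, generation = 7))
    ph <- simulate_phenotypes(gm, data.frame(chrom = "1A", pos_bp = map$pos_bp[2],
                                             a = 1.05),
                              env_effects = c(E1 = .4, E2 = -.2, E3 = .1, E4 = -.3),
                              residual_sd = 0.9)
    cls <- gm$calls[, 2]
    keep <- cls %in% c("A", "B")
    et <- effect_table(ph[ph$line_id %in% names(cls)[keep], ],
                       classifier = cls, baseline = "A", comparison = "B")
    if (abs(et$difference - 2.1) <= 0.3) ok <- ok + 1L
  }
  expect_gte(ok / nsim, 0.90)
})
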