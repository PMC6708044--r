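test_that("frequency tables reproduce the published panel percentages", {
  counts <- wapo_haplotype_counts()
  ft <- frequency_table(list(spring_panel = counts$spring_panel))
  expect_equal(ft$count, c(40L, 198L))
  expect_equal(ft$total, c(238L, 238L))
  expect_equal(ft$percent[ft$allele == "H1"], 16.8)
  expect_equal(ft$percent[ft$allele == "H2"], 83.2)
  # single-allele group is 100%; percentages recompute from counts exactly
  one <- frequency_table(data.frame(group = "g", allele = rep("a", 7)))
  expect_equal(one$percent, 100)
  set.seed(51)
  d <- data.frame(group = sample(c("x", "y"), 200, TRUE),
                  allele = sample(c("a", "b", "c"), 200, TRUE))
  ft2 <- frequency_table(d)
  expect_equal(ft2$percent,
               round_half_up(100 * ft2$count / ft2$total, 1))
  for (g in unique(ft2$group))
    expect_lt(abs(sum(ft2$percent[ft2$group == g]) - 100), 0.1 * 3)
})

test_that("homogeneity chi-square matches the textbook formula and is invariant", {
  m <- rbind(c(10, 90), c(30, 70))
  got <- chi2_homogeneity(m)
  # hand calculation: expected 20/80 per row, chi2 = 2*(100/20 + 100/80)
  expect_equal(got$chi2, 12.5)
  expect_equal(got$df, 1)
  expect_equal(got$p, pchisq(12.5, 1, lower.tail = FALSE))
  # equal proportions: chi2 exactly 0, p = 1
  eq <- chi2_homogeneity(rbind(c(20, 40), c(10, 20)))
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  # permutation invariance and linear scaling on random tables
  set.seed(52)
  for (k in 1:20) {
    t0 <- matrix(rpois(6, 30) + 1, 2, 3)
    a <- chi2_homogeneity(t0)
    b <- chi2_homogeneity(t0[sample(1:2), sample(1:3)])
    expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
    expect_equal(chi2_homogeneity(t0 * 3)$chi2, 3 * a$chi2, tolerance = 1e-9)
  }
  expect_error(chi2_homogeneity(rbind(c(0, 0), c(1, 2))), "margin")
  # agreement with the uncorrected stats implementation
  ref <- suppressWarnings(chisq.test(m, correct = FALSE))
  expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("the null rejection rate of the homogeneity test is calibrated", {
  set.seed(53)
  nsim <- 1e4
  n1 <- 120; n2 <- 150; p0 <- 0.4
  x1 <- rbinom(nsim, n1, p0); x2 <- rbinom(nsim, n2, p0)
  # vectorized 2x2 chi-square (no continuity correction)
  a <- x1; b <- n1 - x1; c <- x2; d <- n2 - x2
  N <- n1 + n2
  chi2 <- N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  rej <- mean(pchisq(chi2, 1, lower.tail = FALSE) < 0.05)
  expect_lt(abs(rej - 0.05), 0.01)
  # spot-check the vectorized formula against the package function
  i <- which.max(chi2)
  expect_equal(chi2_homogeneity(rbind(c(a[i], b[i]), c(c[i], d[i])))$chi2,
               chi2[i], tolerance = 1e-9)
})

test_that("effect tables carry the printed grain-yield arithmetic", {
  # printed differences over printed baselines, at printed precision
  expect_equal(percent_difference(289.5, 4141), 7.0)
  expect_equal(percent_difference(90.8, 4350), 2.1)
  expect_equal(percent_difference(0, 123), 0)
  eff <- wapo_effect_summary()
  gy <- eff[eff$trait == "GY", ]
  expect_equal(percent_difference(gy$difference[gy$panel == "BxR"],
                                  gy$h1_mean[gy$panel == "BxR"]), 7.0)
  expect_equal(percent_difference(gy$difference[gy$panel == "GWAS"],
                                  gy$h1_mean[gy$panel == "GWAS"]), 2.1)
})

test_that("effect_table recovers a simulated haplotype gap across traits", {
  set.seed(54)
  map <- tiny_map(n = 3, spacing_cM = 30)
  gm <- simulate_population(cross_design("RIL_self", 100, map, generation = 7))
  q <- data.frame(chrom = "1A", pos_bp = map$pos_bp[2], a = 1.05)
  ph <- simulate_phenotypes(gm, q, env_effects = c(E1 = .5, E2 = -.5),
                            residual_sd = 0.9)
  cls <- gm$calls[, 2]
  cls[cls == "H"] <- NA
  et <- effect_table(ph, classifier = cls, baseline = "A", comparison = "B")
  expect_equal(et$trait, "SNS")
  expect_lt(abs(et$difference - 2.1), 0.5)
  expect_equal(et$percent_difference,
               percent_difference(et$difference, et$baseline_mean))
  expect_lt(et$p, 0.001)
})

test_that("fold-ACTIN quantification is exact and monotone", {
  expect_equal(fold_actin(25, 25), 1)
  expect_equal(fold_actin(26, 25), 0.5)
  expect_equal(fold_actin(24, 25), 2)
  cts <- seq(20, 30, by = 0.5)
  expect_true(all(diff(fold_actin(cts, 25)) < 0))
  # efficiency-corrected mode (off by default) uses base 1 + eff
  expect_equal(fold_actin(24, 25, efficiency = 0.92), 1.92)
  expect_error(fold_actin(-1, 25), "positive")
})

test_that("group expression comparisons separate a threefold difference", {
  set.seed(55)
  # two genotype groups, true fold ratio 3, four reps, SD 0.3 CT
  hits <- 0L
  nsim <- 200
  for (s in seq_len(nsim)) {
    rec <- data.frame(group = rep(c("allele_b", "allele_a"), each = 4),
                      ct_actin = 20,
                      ct_target = 20 - c(rnorm(4, 1 + log2(3), 0.3),
                                         rnorm(4, 1, 0.3)))
    cmp <- expression_comparison(rec)
    ratio <- cmp$means$mean_fold[cmp$means$group == "allele_b"] /
      cmp$means$mean_fold[cmp$means$group == "allele_a"]
    if (ratio >= 2 && ratio <= 4.5) hits <- hits + 1L
  }
  expect_gte(hits / nsim, 0.90)
})

test_that("Tukey letters join indistinguishable groups and split clear ones", {
  jitter6 <- c(-0.2, -0.1, 0, 0, 0.1, 0.2)
  # basal and central identical by construction; distal threefold higher
  rec <- data.frame(group = rep(c("basal", "central", "distal"), each = 6),
                    block = rep(rep(c("exp1", "exp2"), each = 3), 3),
                    ct_actin = 20,
                    ct_target = 20 - rep(c(0, 0, 3), each = 6) + rep(jitter6, 3))
  cmp <- expression_comparison(rec)
  lab <- setNames(cmp$means$letters, cmp$means$group)
  expect_false(grepl(lab[["distal"]], lab[["basal"]], fixed = TRUE))
  expect_identical(lab[["basal"]], lab[["central"]])
  # three identical groups share a single letter
  rec2 <- data.frame(group = rep(c("g1", "g2", "g3"), each = 6),
                     ct_actin = 20, ct_target = 19 + rep(jitter6, 3))
  cmp2 <- expression_comparison(rec2)
  expect_equal(length(unique(cmp2$means$letters)), 1)
})
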