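#!/usr/bin/env Rscript
# Stage 5 — allele/haplotype frequencies across panels, the landrace-vs-
# cultivar homogeneity test on a synthetic global collection, the
# multi-environment effect table, and the qPCR expression contrast.

library(hifmapr)
set.seed(105)
dir.create("results", showWarnings = FALSE)

# reference panel frequencies
counts <- wapo_haplotype_counts()
ft <- frequency_table(list(spring_panel = counts$spring_panel,
                           exome_hexaploid = counts$exome_hexaploid))
print(ft)
write.csv(ft, "results/panel_frequencies.csv", row.names = FALSE)

# homogeneity test on a synthetic landrace/cultivar split (a-allele carriers
# enriched in landraces, as domestication panels typically show)
tab <- rbind(landraces = c(a = 131, b = 116, c = 10),
             cultivars = c(a = 133, b = 242, c = 12))
chi <- chi2_homogeneity(tab)
message(sprintf("homogeneity chi2 = %.2f, df = %d, P = %.2g",
                chi$chi2, chi$df, chi$p))

# effect table on the simulated RIL trial (classifier: locus marker)
map <- read_marker_map("results/simdata/map.tsv", map_function = "haldane")
ril <- read_genotype_csv("results/simdata/ril_genotypes.csv", map)
ph <- read_phenotype_csv("results/simdata/ril_phenotypes.csv")
cls <- ril$calls[, "IWA5913"]
cls[cls == "H"] <- NA
eff <- effect_table(ph, classifier = cls, baseline = "A", comparison = "B")
message("effect of the locus marker classification (environments as blocks):")
print(eff)
write.csv(eff, "results/effect_table.csv", row.names = FALSE)

# expression contrast between near-isogenic allele carriers: the deletion
# allele transcribes about threefold lower
rec <- data.frame(group = rep(c("allele_b", "allele_a"), each = 4),
                  ct_actin = 20,
                  ct_target = 20 - c(rnorm(4, 1 + log2(3), 0.3),
                                     rnorm(4, 1, 0.3)))
cmp <- expression_comparison(rec)
message("fold-ACTIN transcript levels with Tukey letters:")
print(cmp$means)
write.csv(cmp$means, "results/expression_comparison.csv", row.names = FALSE)
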