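#!/usr/bin/env Rscript
# Stage 2 — Haley-Knott interval mapping of the simulated RIL trial:
# single-QTL LOD curves at the LOD 2.0 threshold, then the joint multi-QTL
# drop-one fit for per-QTL effects and percent variance explained.

library(hifmapr)
set.seed(102)
dir.create("results", showWarnings = FALSE)

map <- read_marker_map("results/simdata/map.tsv", map_function = "haldane")
ril <- read_genotype_csv("results/simdata/ril_genotypes.csv", map)
ph <- read_phenotype_csv("results/simdata/ril_phenotypes.csv")
y <- tapply(ph$value, ph$line_id, mean)   # environment-averaged line means

probs <- conditional_genotype_probs(ril, "RIL_self", step = 1)
curve <- hk_scan(probs, y)
write.csv(as.data.frame(curve), "results/qtl_scan_lod_curve.csv",
          row.names = FALSE)

peaks <- find_peaks(curve, threshold = 2.0, drop = 1.5)
message(sprintf("%d QTL peak(s) above LOD 2.0:", nrow(peaks)))
print(peaks[, c("chrom", "pos_bp", "LOD", "effect", "pve")])

fit <- multi_qtl_fit(probs, y, peaks[, c("chrom", "pos_bp")])
message(sprintf("joint additive model: total PVE %.1f%%", 100 * fit$total_pve))
print(fit$qtl)
write.csv(fit$qtl, "results/qtl_scan_mqm.csv", row.names = FALSE)
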