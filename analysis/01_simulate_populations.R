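#!/usr/bin/env Rscript
# Stage 1 — build the 7AL worked-example map, calibrate the genetic scale to
# the observed screening yield, and simulate the three population types the
# later stages consume (F2 screening progeny, RILs, HIF families).

library(hifmapr)
set.seed(101)
dir.create("results/simdata", showWarnings = FALSE, recursive = TRUE)

iv <- wapo_region_intervals()
cmmb <- calibrate_cm_per_mb(interval_width(iv$bxr_initial), 74 / 617,
                            kind = "haldane")
message(sprintf("calibrated genetic scale: %.3f cM/Mb over the %s window",
                cmmb, format_mb(interval_width(iv$bxr_initial))))
map <- demo_map(cmmb)
write_marker_map(map, "results/simdata/map.tsv")

# F2 screening population between the outer flanking markers
f2 <- simulate_population(cross_design("F2", 617, map))
scr <- find_recombinants(f2, "IWB713", "IWB53096")
message(sprintf("simulated phase-1 screen: %d/%d plants recombinant (%.1f%%)",
                length(scr$recombinant), 617, 100 * scr$fraction))
write_genotype_csv(f2, "results/simdata/f2_screen_genotypes.csv")

# RIL population carrying the main locus plus the two background QTLs
ril <- simulate_population(cross_design("RIL_self", 200, map, generation = 7))
defs <- sns_defaults()
qtls <- data.frame(chrom = c("7A", "2BS", "7AS"),
                   pos_bp = c(674080862, 1e7, 2e7),
                   a = c(defs$a_main, defs$background$a))
ph <- simulate_phenotypes(ril, qtls,
                          env_effects = c(Dav_irr = 0.6, Dav_dry = -0.4,
                                          Imp_irr = 0.3, Imp_dry = -0.5),
                          reps_per_env = 2, residual_sd = defs$residual_sd)
write_genotype_csv(ril, "results/simdata/ril_genotypes.csv")
write_phenotype_csv(ph, "results/simdata/ril_phenotypes.csv")
h2 <- realized_heritability(ph)
message(sprintf("RIL trait: realized line-mean H2 = %.2f over 4 environments",
                h2$H2))

# HIF families segregating only near the locus; founders are screened
# recombinants heterozygous at the proximal marker, so some families end up
# homozygous at the locus itself — that contrast is what Mendelizes it
hif <- simulate_population(
  cross_design("HIF", 8, map, generation = 5,
               hif = list(family_size = 40, target = "IWB6693",
                          region = map$name[map$chrom == "7A"],
                          require_breakpoint = TRUE)))

# the variance contrast that motivates HIFs: polygenic background segregates
# between RILs but is fixed within a family, so RIL-level trials carry a much
# larger pooled SD than HIF progeny tests
ril_field <- simulate_phenotypes(ril, qtls,
                                 env_effects = c(E1 = 0), reps_per_env = 2,
                                 residual_sd = defs$residual_sd,
                                 polygenic_sd = defs$polygenic_sd,
                                 polygenic_exclude_chrom = "7A")
cls <- ril$calls[, "IWA5913"]
ril_sd <- sqrt(mean(tapply(ril_field$value, cls[ril_field$line_id], var),
                    na.rm = TRUE))
fam1 <- hif$pedigree$member_id[hif$pedigree$family_id == "F01"]
hif_field <- simulate_phenotypes(
  list(calls = hif$members$calls[fam1, ], map = map) |>
    structure(class = "genotype_matrix"),
  qtls, env_effects = c(E1 = 0), reps_per_env = 2,
  residual_sd = defs$residual_sd, polygenic_sd = defs$polygenic_sd,
  polygenic_exclude_chrom = "7A")
hcls <- hif$members$calls[fam1, "IWA5913"]
hif_sd <- sqrt(mean(tapply(hif_field$value, hcls[hif_field$line_id], var),
                    na.rm = TRUE))
message(sprintf("pooled SD: RIL trial %.2f vs HIF progeny test %.2f (%.1fx)",
                ril_sd, hif_sd, ril_sd / hif_sd))
write_genotype_csv(hif$founders, "results/simdata/hif_founders.csv")
write_genotype_csv(hif$members, "results/simdata/hif_members.csv")
write.csv(hif$pedigree, "results/simdata/hif_pedigree.csv", row.names = FALSE)
message(sprintf("simulated %d HIF families x %d sister lines",
                nrow(hif$founders$calls), 40))
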