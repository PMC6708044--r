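#!/usr/bin/env Rscript
# Stage 3 — Mendelize the locus with the HIF families: progeny-test each
# family's homozygous sister lines in two blocked experiments, classify
# heterozygous/homozygous, deduce the candidate interval from the breakpoint
# constraints, and plan the next screening phase.

library(hifmapr)
set.seed(103)
dir.create("results", showWarnings = FALSE)

map <- read_marker_map("results/simdata/map.tsv", map_function = "haldane")
region <- map$name[map$chrom == "7A"]
founders <- read_genotype_csv("results/simdata/hif_founders.csv", map)
members <- read_genotype_csv("results/simdata/hif_members.csv", map)
pedigree <- read.csv("results/simdata/hif_pedigree.csv",
                     stringsAsFactors = FALSE)
hif <- list(founders = founders, members = members, pedigree = pedigree)

progeny <- simulate_progeny_tests(hif, map, locus_marker = "WAPO-A1",
                                  reps = 25)
write_phenotype_csv(progeny, "results/fine_mapping_progeny_tests.csv")

fams <- lapply(unique(progeny$family_id), function(fid) {
  fam <- recombinant_family(fid, founders$calls[fid, region], map)
  test <- progeny_test_classify(progeny[progeny$family_id == fid, ],
                                alpha = 0.05)
  message(sprintf("family %s: F = %6.1f, P = %.2g -> %s", fid, test$F,
                  test$p, test$classification))
  list(family = fam, classification = test$classification, test = test)
})

ded <- deduce_locus_interval(fams)
message("deduced candidate interval:")
print(ded$candidate_interval)
true_bp <- map$pos_bp[map$name == "WAPO-A1"]
message(sprintf("contains the simulated locus (%s bp): %s",
                format(true_bp, big.mark = ","),
                any(vapply(ded$pieces, interval_contains, logical(1),
                           pos_bp = true_bp))))

cmmb <- calibrate_cm_per_mb(
  interval_width(wapo_region_intervals()$bxr_initial), 74 / 617,
  kind = "haldane")
plan <- plan_rescreen(ded$candidate_interval, cmmb, target = 5,
                      kind = "haldane", n_planned = 1208)
message(sprintf(
  "rescreen plan: expected recombinant fraction %.4f; %d plants for 5 new events; P(zero in 1208) = %.3f",
  plan$p_recombinant, plan$n_required, plan$p_zero))

jsonlite::write_json(
  list(candidate_interval = list(chrom = ded$candidate_interval$chrom,
                                 start_bp = ded$candidate_interval$start_bp,
                                 end_bp = ded$candidate_interval$end_bp,
                                 width = format_bp(interval_width(ded$candidate_interval))),
       classifications = vapply(fams, `[[`, character(1), "classification"),
       conflicts = ded$conflicts,
       rescreen = plan),
  "results/fine_mapping_deduction.json", auto_unbox = TRUE, digits = 8,
  pretty = TRUE)
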