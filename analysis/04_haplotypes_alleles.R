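#!/usr/bin/env Rscript
# Stage 4 — haplotype-block structure and diagnostic allele classification:
# four-gamete blocks over a synthetic accession panel mirroring the reference
# panel's H1/H2/H3 group sizes, then the published diagnostic profiles
# through the allele classifier and the dual-population candidate filter.

library(hifmapr)
set.seed(104)
dir.create("results", showWarnings = FALSE)

# synthetic SNP panel over the block: three haplotype patterns at the
# reference panel's 33/13/3 frequencies plus one historical recombinant
# whose h1/h2 junction between sites 6 and 7 creates all four gametes there
p <- 12
h1 <- rbinom(p, 1, 0.5)
h2 <- 1 - h1                                   # polymorphic at every site
h3 <- c(h1[1:6], 1 - h1[7:p])
panel <- rbind(matrix(h2, 33, p, byrow = TRUE),
               matrix(h1, 13, p, byrow = TRUE),
               matrix(h3, 3, p, byrow = TRUE),
               c(h2[1:6], h1[7:p]))
rownames(panel) <- c(sprintf("cv%02d", 1:49), "recombinant1")
snps <- snp_matrix(panel, pos_bp = 672e6 + (seq_len(p) - 1) * 2e5)

blocks <- four_gamete_block_boundaries(snps)
message(sprintf("four-gamete test: %d block(s)", nrow(blocks)))
print(blocks)
write.csv(blocks, "results/haplotype_blocks.csv", row.names = FALSE)

hap <- assign_haplotypes(snps, max_missing = 0.2)
message("haplotype group sizes (49 reference cultivars + 1 recombinant):")
print(hap$groups[, c("haplotype", "size")])
write.csv(hap$assignment, "results/haplotype_assignment.csv", row.names = FALSE)

# diagnostic allele classification of the published profiles
ref <- wapo_allele_reference()
calls <- classify_wapo_allele(ref)
print(calls[, c("accession_group", "expected_allele", "allele")])
write.csv(calls, "results/allele_calls.csv", row.names = FALSE)

# candidate filter over the polymorphism table, restricted to the 87-kb region
filt <- candidate_polymorphism_filter(wapo_candidate_polymorphisms(),
                                      region = wapo_region_intervals()$candidate)
message(sprintf("candidate gene(s) after the dual-population filter: %s",
                paste(filt$candidates, collapse = ", ")))
print(filt$excluded)
jsonlite::write_json(filt, "results/candidate_gene_report.json",
                     auto_unbox = TRUE, pretty = TRUE)

# the two diagnostic assays
message(sprintf("promoter indel amplicons: P- %d bp, P+ %d bp",
                predict_amplicon_sizes(210, 115, TRUE),
                predict_amplicon_sizes(210, 115, FALSE)))
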