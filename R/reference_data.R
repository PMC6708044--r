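# Published reference inputs for the wheat 7AL spikelet-number locus
# (RefSeq v1.0 coordinates). These ship as plain data constructors so the
# interval arithmetic, filters and frequency analyses can be exercised on
# the real worked example without any download.

#' Marker-bounded intervals of the 7AL fine-mapping campaign
#'
#' Flanking-marker coordinates of each mapping stage: the initial screening
#' windows of the two biparental populations, the phase-1/round-1 reductions,
#' the final 87-kb candidate interval, and the 2.3-Mb haplotype block.
#'
#' @return named list of [genomic_interval()]s with a `markers` attribute
#'   giving the flanking marker names per interval.
#' @export
wapo_region_intervals <- function() {
  iv <- list(
    bxr_initial     = genomic_interval("7A", 670767495, 679896953),  # IWB713 - IWB53096
    nxc_initial     = genomic_interval("7A", 671218901, 679955879),  # IWB7435 - IWA5167
    bxr_phase1      = genomic_interval("7A", 673779017, 674276906),  # Traes1400-I4V - IWA5913
    nxc_round1      = genomic_interval("7A", 673854124, 674276906),  # AX-109397893 - IWA5913
    candidate       = genomic_interval("7A", 674019191, 674106327),  # AX-111159341 - AX-109360122
    haplotype_block = genomic_interval("7A", 672000000, 674300000))
  attr(iv, "markers") <- list(
    bxr_initial = c("IWB713", "IWB53096"),
    nxc_initial = c("IWB7435", "IWA5167"),
    bxr_phase1 = c("Traes1400-I4V", "IWA5913"),
    nxc_round1 = c("AX-109397893", "IWA5913"),
    candidate = c("AX-111159341", "AX-109360122"))
  iv
}

#' The 115-bp promoter deletion as a sequence feature
#'
#' Coordinates relative to the start codon: -599 to -485, inclusive.
#'
#' @return a feature-kind [genomic_interval()] (positions offset by +1000 so
#'   they stay positive; widths are unaffected) with attribute
#'   `promoter_offsets` carrying the original -599/-485 pair.
#' @export
wapo_promoter_deletion <- function() {
  iv <- genomic_interval("WAPO-A1_promoter", -599 + 1000, -485 + 1000,
                         kind = "feature")
  attr(iv, "promoter_offsets") <- c(-599, -485)
  iv
}

#' Screening sizes and recombinant yields of the fine-mapping campaign
#'
#' @return nested list of plant counts: per population, plants screened per
#'   phase and recombinants recovered.
#' @export
wapo_screening_counts <- function() {
  list(
    bxr = list(phase1_screened = 617, phase1_recombinants = 74,
               phase2_screened = 1208, phase2_recombinants = 0,
               progeny_test_families = 4),
    nxc = list(screened = c(4219, 2277), extra_screened = 3948,
               recombinants = 93, recombinant_classes = 31,
               progeny_test_families = 5))
}

#' Haplotype counts of the reference panels
#'
#' Group sizes of the three 2.3-Mb haplotypes in the exome-capture set of
#' hexaploid cultivars (H2 = 33, H1 = 13, H3 = 3) and the H1/H2 counts in
#' the 238-line spring wheat panel.
#'
#' @return list with `exome_hexaploid` (named counts) and `spring_panel`.
#' @export
wapo_haplotype_counts <- function() {
  list(exome_hexaploid = c(H2 = 33L, H1 = 13L, H3 = 3L),
       exome_tetraploid = c(H1 = 4L),
       spring_panel = c(H1 = 40L, H2 = 198L))
}

#' Candidate-region polymorphisms between haplotype parents
#'
#' The polymorphism table over the high-confidence genes around the
#' candidate interval: each row is a position with its effect class in the
#' H2-vs-H1 contrast (Berkut vs RAC875) and the H2-vs-H3 contrast (MPV57 vs
#' LA95135). Effect classes: `none` (not polymorphic), `synonymous`,
#' `non_synonymous`, `promoter` (promoter indel).
#'
#' @return data.frame with columns `gene_id`, `pos_bp`, `h2_vs_h1`,
#'   `h2_vs_h3`, `change`, `annotation`.
#' @export
wapo_candidate_polymorphisms <- function() {
  r <- function(gene, pos, c1, c2, change, ann)
    data.frame(gene_id = gene, pos_bp = pos, h2_vs_h1 = c1, h2_vs_h3 = c2,
               change = change, annotation = ann, stringsAsFactors = FALSE)
  rbind(
    r("TraesCS7A02G481400", 673779017, "non_synonymous", "non_synonymous",
      "I4V", "CYTOCHROME C OXIDASE SUBUNIT 6A"),
    r("TraesCS7A02G481500", 674018426, "none", "non_synonymous",
      "R207G", "AMIDOHYDROLASE"),
    r("TraesCS7A02G481500", 674019603, "synonymous", "none", "", "AMIDOHYDROLASE"),
    r("TraesCS7A02G481500", 674019951, "synonymous", "synonymous", "", "AMIDOHYDROLASE"),
    r("TraesCS7A02G481500", 674020022, "non_synonymous", "none",
      "V456A", "AMIDOHYDROLASE"),
    r("TraesCS7A02G481600", 674080862, "promoter", "none",
      "P+/P- (115-bp del)", "ABERRANT PANICLE ORGANIZATION 1"),
    r("TraesCS7A02G481600", 674081601, "non_synonymous", "non_synonymous",
      "C47F", "ABERRANT PANICLE ORGANIZATION 1"),
    r("TraesCS7A02G481600", 674082745, "non_synonymous", "none",
      "D384N", "ABERRANT PANICLE ORGANIZATION 1"),
    r("TraesCS7A02G481700", 674091310, "synonymous", "none", "",
      "MAJOR POLLEN ALLERGEN OLE E 10-LIKE"),
    r("TraesCS7A02G481700", 674091312, "none", "non_synonymous",
      "L177H", "MAJOR POLLEN ALLERGEN OLE E 10-LIKE"),
    r("TraesCS7A02G481800", 674106471, "synonymous", "none", "", "SYNTAXIN"),
    r("TraesCS7A02G481900", 674115185, "none", "non_synonymous",
      "E46A", "CASP-LIKE PROTEIN 5B3"),
    r("TraesCS7A02G482000", 674272225, "non_synonymous", "none",
      "E252*", "HYDROLASE"),
    r("TraesCS7A02G482100", 674274282, "synonymous", "none", "",
      "DETOXIFICATION 34-LIKE"),
    r("TraesCS7A02G482100", 674274822, "none", "synonymous", "",
      "DETOXIFICATION 34-LIKE"))
}

#' Published haplotype-effect summary (LS means by marker IWA5913)
#'
#' Least-squares means (environments as blocks) for carriers of the H2
#' (Berkut-type) and H1 (RAC875-type) haplotypes in the six-environment
#' GWAS panel and the four-environment Berkut x RAC875 RIL trial, for
#' spikelet number per spike (SNS), kernel weight (KW, mg) and grain yield
#' (GY, kg/ha), plus the printed H2 - H1 differences.
#'
#' @return data.frame with columns `panel`, `trait`, `h2_mean`, `h1_mean`,
#'   `difference` (printed H2 - H1 row).
#' @export
wapo_effect_summary <- function() {
  data.frame(
    panel = rep(c("GWAS", "BxR"), each = 3),
    trait = rep(c("SNS", "KW", "GY"), 2),
    h2_mean = c(20.7, 33.6, 4441, 19.8, 55.2, 4431),
    h1_mean = c(19.7, 34.3, 4350, 17.7, 52.9, 4141),
    difference = c(0.9, -0.89, 90.8, 2.10, 2.2, 289.5),
    stringsAsFactors = FALSE)
}
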