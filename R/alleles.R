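LINKED_SNP_KEYS <- c("c397", "c787", "c974", "g764", "cneg66",
                     "g460", "a244", "g134", "t842")

#' Classify WAPO-A1 alleles from diagnostic polymorphisms
#'
#' Deterministic, total classification of the wheat 7AL spikelet-number gene
#' alleles from the diagnostic marker calls: the 115-bp promoter indel
#' (`P_plus` / `P_minus`), the codon-47 dCAPS (`C`/`F`), the codon-384 change
#' (`D`/`N`) and the linked diagnostic SNPs. Rules, in order:
#'
#' * contradictory evidence (`P_minus` with `F47`, `N384` with `P_plus` or
#'   `F47`, `D384` with `P_minus`, or c- and d-diagnostic SNPs together) ->
#'   `inconsistent`;
#' * `P_minus` with codon 47 not `F` -> `WAPO-A1a` (the only deletion
#'   allele; `N384` is confirmatory, not required — the PCR assay uses only
#'   P-/C47);
#' * `F47` -> `WAPO-A1b` (the only F47 allele);
#' * `P_plus`/`C47` with a c-diagnostic SNP (`c397 = T`, `c787 = T` or
#'   `c974 = G`) -> `WAPO-A1c`; with a d-diagnostic SNP (`g764 = A` or
#'   `cneg66 = T`) -> `WAPO-A1d`;
#' * `P_plus`/`C47` with no informative linked SNP -> `ancestral_unresolved`
#'   (the ancestral P+/C47/D384 consensus);
#' * everything still undecided (e.g. both core markers missing) ->
#'   `ancestral_unresolved`.
#'
#' `inconsistent` is a value, never an error.
#'
#' @param g a data.frame with columns `promoter_indel` (`P_plus`, `P_minus`
#'   or `NA`), `codon47` (`C`, `F`, `NA`), `codon384` (`D`, `N`, `NA`) and
#'   optionally the linked-SNP columns
#'   `c397,c787,c974,g764,cneg66,g460,a244,g134,t842`.
#' @return data.frame `g` with columns `allele` and `evidence` appended.
#' @export
classify_wapo_allele <- function(g) {
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  need <- c("promoter_indel", "codon47", "codon384")
  for (cc in need) if (is.null(g[[cc]])) g[[cc]] <- NA_character_
  extra <- setdiff(intersect(names(g), LINKED_SNP_KEYS), character(0))
  n <- nrow(g)
  allele <- character(n); evidence <- character(n)
  get <- function(col, i) if (col %in% names(g)) g[[col]][i] else NA_character_
  for (i in seq_len(n)) {
    p <- g$promoter_indel[i]; c47 <- g$codon47[i]; c384 <- g$codon384[i]
    c_diag <- isTRUE(get("c397", i) == "T") || isTRUE(get("c787", i) == "T") ||
      isTRUE(get("c974", i) == "G")
    d_diag <- isTRUE(get("g764", i) == "A") || isTRUE(get("cneg66", i) == "T")
    ev <- c(if (!is.na(p)) p, if (!is.na(c47)) paste0(c47, "47"),
            if (!is.na(c384)) paste0(c384, "384"),
            if (c_diag) "c-linked SNP", if (d_diag) "d-linked SNP")
    contradictory <-
      (isTRUE(p == "P_minus") && isTRUE(c47 == "F")) ||
      (isTRUE(c384 == "N") && (isTRUE(p == "P_plus") || isTRUE(c47 == "F"))) ||
      (isTRUE(c384 == "D") && isTRUE(p == "P_minus")) ||
      (c_diag && d_diag) ||
      ((c_diag || d_diag) && (isTRUE(p == "P_minus") || isTRUE(c47 == "F")))
    allele[i] <- if (contradictory) {
      "inconsistent"
    } else if (isTRUE(p == "P_minus")) {
      "WAPO-A1a"
    } else if (isTRUE(c47 == "F")) {
      "WAPO-A1b"
    } else if (isTRUE(c384 == "N")) {
      "WAPO-A1a"   # N384 is unique to the deletion allele
    } else if (c_diag) {
      "WAPO-A1c"
    } else if (d_diag) {
      "WAPO-A1d"
    } else {
      "ancestral_unresolved"
    }
    evidence[i] <- paste(ev, collapse = "/")
  }
  g$allele <- allele
  g$evidence <- evidence
  g
}

#' Diagnostic profiles of the four WAPO-A1 alleles and the consensus
#'
#' The published natural-variation table for the gene: promoter indel,
#' codon-47 and codon-384 states and the nine linked diagnostic SNPs for
#' alleles a-d (haplotypes H1, H2 and the two H3 alleles) plus the ancestral
#' consensus.
#'
#' @return data.frame with one row per allele, diagnostic columns, and the
#'   expected classification in `expected_allele`.
#' @export
wapo_allele_reference <- function() {
  data.frame(
    accession_group = c("H1 (RAC875, Clark)", "H2 (Berkut, Ning7840)",
                        "H3 emmer-type", "H3 durum-type", "ancestral consensus"),
    expected_allele = c("WAPO-A1a", "WAPO-A1b", "WAPO-A1c", "WAPO-A1d",
                        "ancestral_unresolved"),
    promoter_indel = c("P_minus", "P_plus", "P_plus", "P_plus", "P_plus"),
    codon47 = c("C", "F", "C", "C", "C"),
    codon384 = c("N", "D", "D", "D", "D"),
    g460 = c("G", "A", "G", "G", "G"),
    a244 = c("A", "G", "A", "A", "A"),
    g134 = c("G", "T", "G", "G", "G"),
    cneg66 = c("C", "C", "C", "T", "C"),
    c397 = c("C", "C", "T", "C", "C"),
    g764 = c("G", "G", "G", "A", "G"),
    c787 = c("C", "C", "T", "C", "C"),
    t842 = c("T", "C", "T", "T", "T"),
    c974 = c("C", "C", "G", "C", "C"),
    stringsAsFactors = FALSE)
}

#' Dual-population candidate polymorphism filter
#'
#' A gene in the candidate region can explain a trait difference observed in
#' both an H2 x H1 and an H2 x H3 population only if it carries a functional
#' polymorphism (non-synonymous change or promoter indel) that differentiates
#' H2 from H1 *and* from H3 at the same position. Genes whose polymorphisms
#' are synonymous-only or segregate in a single contrast are excluded, with
#' per-gene reasons.
#'
#' @param table data.frame with columns `gene_id`, `pos_bp`, `h2_vs_h1`,
#'   `h2_vs_h3` (each in `none/synonymous/non_synonymous/promoter`) and
#'   optionally `annotation` (see [wapo_candidate_polymorphisms()]).
#' @param region optional [genomic_interval()]; only positions strictly
#'   inside its marker bounds are considered (the flanking-marker positions
#'   themselves are recombination breakpoints, not candidates).
#' @return list with `candidates` (gene ids), `support` (qualifying rows),
#'   `excluded` (data.frame gene_id, reason).
#' @export
candidate_polymorphism_filter <- function(table, region = NULL) {
  if (nrow(table) == 0)
    return(list(candidates = character(0), support = table,
                excluded = data.frame(gene_id = character(0),
                                      reason = character(0))))
  ok_class <- c("non_synonymous", "promoter")
  tab <- table
  if (!is.null(region))
    tab <- tab[interval_contains(region, tab$pos_bp, open = TRUE), , drop = FALSE]
  qual <- tab$h2_vs_h1 %in% ok_class & tab$h2_vs_h3 %in% ok_class
  cand <- unique(tab$gene_id[qual])
  excluded <- NULL
  for (gid in setdiff(unique(tab$gene_id), cand)) {
    rows <- tab[tab$gene_id == gid, , drop = FALSE]
    reason <- if (any(rows$h2_vs_h1 %in% ok_class) ||
                  any(rows$h2_vs_h3 %in% ok_class))
      "functional change in a single contrast only"
    else if (any(rows$h2_vs_h1 == "synonymous" | rows$h2_vs_h3 == "synonymous"))
      "synonymous changes only"
    else "no polymorphism in the contrasts"
    excluded <- rbind(excluded, data.frame(gene_id = gid, reason = reason,
                                           stringsAsFactors = FALSE))
  }
  list(candidates = cand, support = tab[qual, , drop = FALSE],
       excluded = excluded %||% data.frame(gene_id = character(0),
                                           reason = character(0)))
}

#' PCR amplicon size for an indel marker
#'
#' The deletion allele amplifies the base fragment; alleles without the
#' deletion carry `indel_len` extra bases.
#'
#' @param base_size_without_indel amplicon size (bp) for the deletion allele.
#' @param indel_len indel length in bp.
#' @param allele_has_indel `TRUE` when the allele carries the deletion.
#' @return amplicon size in bp.
#' @examples
#' predict_amplicon_sizes(210, 115, TRUE)   # 210 (P- allele)
#' predict_amplicon_sizes(210, 115, FALSE)  # 325 (P+ alleles)
#' @export
predict_amplicon_sizes <- function(base_size_without_indel, indel_len,
                                   allele_has_indel) {
  assert_that(all(base_size_without_indel > 0) && all(indel_len >= 0),
              "sizes must be positive")
  base_size_without_indel + ifelse(allele_has_indel, 0, indel_len)
}
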