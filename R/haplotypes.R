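#' Construct a SNP matrix over a genomic window
#'
#' Accessions x ordered biallelic sites, alleles coded 0/1 with `NA` for
#' missing; site positions strictly increasing in bp.
#'
#' @param geno numeric/integer matrix of 0/1/NA (accessions in rows).
#' @param pos_bp site positions (columns), strictly increasing.
#' @param accessions accession ids (default rownames).
#' @param chrom chromosome label.
#' @return object of class `snp_matrix`.
#' @export
snp_matrix <- function(geno, pos_bp, accessions = rownames(geno), chrom = "7A") {
  geno <- as.matrix(geno)
  assert_that(!is.null(accessions) && !anyDuplicated(accessions),
              "accession ids must be present and unique")
  assert_that(length(pos_bp) == ncol(geno), "pos_bp must match columns")
  assert_that(all(diff(pos_bp) > 0), "site positions must be strictly increasing")
  assert_that(all(geno %in% c(0, 1) | is.na(geno)), "alleles must be 0/1/NA")
  rownames(geno) <- accessions
  colnames(geno) <- as.character(pos_bp)
  structure(list(geno = geno, pos_bp = as.numeric(pos_bp), chrom = chrom),
            class = "snp_matrix")
}

#' Haplotype block boundaries by the four-gamete test
#'
#' A historical recombination event between two adjacent sites is inferred
#' when all four gametes (00, 01, 10, 11) occur among accessions non-missing
#' at both sites; blocks are the maximal runs of sites without such a
#' boundary. Sites that are missing in every accession are skipped with a
#' warning.
#'
#' @param snps a [snp_matrix()].
#' @return data.frame with one row per block: `start_site`, `end_site`
#'   (column indices), `start_bp`, `end_bp`, `n_sites`.
#' @export
four_gamete_block_boundaries <- function(snps) {
  g <- snps$geno
  assert_that(ncol(g) >= 2, "need >= 2 sites")
  allmiss <- colSums(!is.na(g)) == 0
  if (any(allmiss)) warning(sprintf("%d all-missing site(s) skipped", sum(allmiss)))
  usable <- which(!allmiss)
  boundary_after <- logical(ncol(g))
  for (k in seq_len(length(usable) - 1)) {
    i <- usable[k]; j <- usable[k + 1]
    ok <- !is.na(g[, i]) & !is.na(g[, j])
    gam <- unique(paste0(g[ok, i], g[ok, j]))
    if (all(c("00", "01", "10", "11") %in% gam)) boundary_after[i] <- TRUE
  }
  cuts <- which(boundary_after)
  starts <- c(1, cuts + 1)
  ends <- c(cuts, ncol(g))
  data.frame(start_site = starts, end_site = ends,
             start_bp = snps$pos_bp[starts], end_bp = snps$pos_bp[ends],
             n_sites = ends - starts + 1)
}

#' Assign accessions to haplotype groups over a block
#'
#' Accessions with complete (or previously seen) patterns seed the groups;
#' an accession with missing sites joins a group when it matches exactly one
#' group consensus at all its non-missing sites, and is left unassigned when
#' none or several fit, or when its missing fraction exceeds
#' `max_missing`. Groups are labelled H1, H2, ... in descending size with
#' ties broken by the lexicographically smaller consensus; the numbering
#' carries no ancestral meaning, and `anchors` can rename groups after known
#' accessions (e.g. `c(RAC875 = "H1")`).
#'
#' @param snps a [snp_matrix()] restricted to one block.
#' @param max_missing maximum tolerated per-accession missing fraction.
#' @param anchors optional named character vector accession -> desired label.
#' @return object of class `haplotype_assignment`: list with `assignment`
#'   (data.frame accession, haplotype), `groups` (data.frame haplotype, size,
#'   consensus), `n_assigned`.
#' @export
assign_haplotypes <- function(snps, max_missing = 0.2, anchors = NULL) {
  g <- snps$geno
  assert_that(ncol(g) >= 1, "empty block rejected")
  lab <- rep(NA_character_, nrow(g))
  names(lab) <- rownames(g)
  fr_miss <- rowMeans(is.na(g))
  eligible <- fr_miss <= max_missing
  complete <- eligible & rowSums(is.na(g)) == 0
  pat <- apply(g, 1, paste, collapse = "")
  consensi <- unique(pat[complete])
  cons_mat <- do.call(rbind, strsplit(consensi, ""))
  membership <- lapply(consensi, function(s) names(lab)[complete & pat == s])
  for (id in rownames(g)[eligible & !complete]) {
    v <- g[id, ]
    nz <- !is.na(v)
    if (!any(nz) || is.null(cons_mat)) next
    ok <- apply(cons_mat, 1, function(s) all(as.integer(s[nz]) == v[nz]))
    if (sum(ok) == 1) {
      membership[[which(ok)]] <- c(membership[[which(ok)]], id)
    }
  }
  if (length(consensi)) {
    sizes <- lengths(membership)
    o <- order(-sizes, consensi)
    for (k in seq_along(o)) lab[membership[[o[k]]]] <- sprintf("H%d", k)
    groups <- data.frame(haplotype = sprintf("H%d", seq_along(o)),
                         size = sizes[o], consensus = consensi[o],
                         stringsAsFactors = FALSE)
  } else {
    groups <- data.frame(haplotype = character(0), size = integer(0),
                         consensus = character(0))
  }
  if (!is.null(anchors)) {
    map <- setNames(groups$haplotype, groups$haplotype)
    for (acc in names(anchors)) {
      cur <- lab[acc]
      if (!is.na(cur)) map[cur] <- anchors[[acc]]
    }
    assert_that(!anyDuplicated(map[map != names(map)] ),
                "anchors map two groups to the same label")
    lab[!is.na(lab)] <- map[lab[!is.na(lab)]]
    groups$haplotype <- map[groups$haplotype]
  }
  structure(list(assignment = data.frame(accession = names(lab),
                                         haplotype = unname(lab),
                                         stringsAsFactors = FALSE),
                 groups = groups,
                 n_assigned = sum(!is.na(lab))),
            class = "haplotype_assignment")
}
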