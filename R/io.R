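#' Read / write long-format phenotype tables
#'
#' Columns: `line_id`, `environment`, `replicate`, `trait`, `value`.
#'
#' @param path CSV path.
#' @param pheno a phenotype table.
#' @return `read_phenotype_csv()` a data.frame; `write_phenotype_csv()`
#'   `path` invisibly.
#' @rdname phenotype_csv
#' @export
read_phenotype_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "environment", "replicate", "trait", "value")
  assert_that(all(need %in% names(d)),
              "phenotype CSV needs columns %s", paste(need, collapse = ", "))
  assert_that(all(is.finite(d$value)), "phenotype values must be finite")
  d[, need]
}

#' @rdname phenotype_csv
#' @export
write_phenotype_csv <- function(pheno, path) {
  write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read diagnostic marker calls
#'
#' CSV with a `accession` column (and optionally `group`), the core columns
#' `promoter_indel`, `codon47`, `codon384` and any of the linked-SNP columns.
#' Empty cells become `NA`.
#'
#' @param path CSV path.
#' @return data.frame ready for [classify_wapo_allele()].
#' @export
read_diagnostics_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA", "-"))
  assert_that("accession" %in% names(d), "diagnostics CSV needs 'accession'")
  bad <- setdiff(names(d), c("accession", "group", "promoter_indel",
                             "codon47", "codon384", LINKED_SNP_KEYS))
  assert_that(length(bad) == 0, "unknown diagnostic column(s): %s",
              paste(bad, collapse = ", "))
  d
}

#' Read a SNP matrix from CSV
#'
#' First column `accession`; remaining columns named by bp position; cells
#' 0/1 or empty/`-`/`NA` for missing.
#'
#' @param path CSV path.
#' @param chrom chromosome label.
#' @return a [snp_matrix()].
#' @export
read_snp_csv <- function(path, chrom = "7A") {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                na.strings = c("", "NA", "-"))
  assert_that(names(d)[1] == "accession", "first column must be accession")
  g <- as.matrix(d[, -1, drop = FALSE])
  mode(g) <- "numeric"
  snp_matrix(g, as.numeric(colnames(g)), d$accession, chrom)
}

#' Read a SNP matrix from VCF
#'
#' Keeps biallelic SNP records only (multi-allelic and indel records are
#' skipped, with counts reported via message); genotypes are collapsed to
#' 0 (hom ref), 1 (hom alt) and `NA` (missing or heterozygous — accessions
#' here are inbred, so residual hets carry no haplotype information).
#'
#' @param path VCF path (plain or gzipped).
#' @param region_start,region_end optional window bounds in bp. Coordinates
#'   are interpreted 1-based inclusive (the project convention); set
#'   `half_open = TRUE` for BED-style half-open queries, which converts
#'   `[start, end)` to `[start + 1, end]` internally... i.e. `start` is then
#'   0-based exclusive and `end` inclusive.
#' @param half_open whether the query bounds are BED-style half-open.
#' @return a [snp_matrix()].
#' @export
read_snp_vcf <- function(path, region_start = NULL, region_end = NULL,
                         half_open = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  pos <- as.numeric(fix[, "POS"])
  snp <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    !grepl(",", fix[, "ALT"], fixed = TRUE) &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  if (any(!snp))
    message(sum(!snp), " non-biallelic-SNP record(s) skipped")
  keep <- snp
  if (!is.null(region_start)) {
    lo <- if (half_open) region_start + 1 else region_start
    hi <- region_end
    keep <- keep & pos >= lo & pos <= hi
  }
  assert_that(any(keep), "no biallelic SNPs in the requested region")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  num <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  num[gt %in% c("0/0", "0|0", "0")] <- 0
  num[gt %in% c("1/1", "1|1", "1")] <- 1
  chrom <- unique(fix[keep, "CHROM"])
  assert_that(length(chrom) == 1, "region spans several chromosomes")
  o <- order(pos[keep])
  snp_matrix(t(num[o, , drop = FALSE]), sort(pos[keep]),
             colnames(gt), chrom)
}
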