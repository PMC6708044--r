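#' Worked-example marker map of the 7AL region
#'
#' The markers of the published fine-mapping campaign at their RefSeq v1.0
#' positions (plus the candidate gene's promoter position as the simulated
#' locus), with genetic positions derived from the calibrated cM/Mb scalar,
#' and two background chromosomes (2BS, 7AS) carrying the secondary QTLs.
#'
#' @param cm_per_mb cM/Mb scalar for 7A; defaults to the value calibrated so
#'   the initial 9.13-Mb screening window reproduces the observed 12.0%
#'   plant-level recombinant fraction (74 of 617).
#' @return a [marker_map()] (Haldane map function; the simulator's model).
#' @export
demo_map <- function(cm_per_mb = NULL) {
  iv <- wapo_region_intervals()
  cm_per_mb <- cm_per_mb %||%
    calibrate_cm_per_mb(interval_width(iv$bxr_initial), 74 / 617,
                        kind = "haldane")
  m7 <- data.frame(
    name = c("IWB713", "IWB7435", "IWB6693", "Traes1400-I4V", "AX-109397893",
             "AX-111159341", "WAPO-A1", "AX-109360122", "IWA5913",
             "IWB53096", "IWA5167"),
    pos_bp = c(670767495, 671218901, 672032033, 673779017, 673854124,
               674019191, 674080862, 674106327, 674276906,
               679896953, 679955879),
    stringsAsFactors = FALSE)
  bg <- function(chrom, start) data.frame(
    name = sprintf("%s_m%d", chrom, 1:5),
    pos_bp = seq(start, by = 15e6, length.out = 5),
    stringsAsFactors = FALSE)
  b2 <- bg("2BS", 1e7); b7 <- bg("7AS", 2e7)
  name <- c(m7$name, b2$name, b7$name)
  chrom <- c(rep("7A", nrow(m7)), rep("2BS", 5), rep("7AS", 5))
  pos_bp <- c(m7$pos_bp, b2$pos_bp, b7$pos_bp)
  pos_cM <- c((m7$pos_bp - min(m7$pos_bp)) / 1e6 * cm_per_mb,
              (b2$pos_bp - min(b2$pos_bp)) / 1e6 * 1,
              (b7$pos_bp - min(b7$pos_bp)) / 1e6 * 1)
  marker_map(name, chrom, pos_bp, pos_cM, map_function = "haldane")
}

default_pipeline_config <- function() {
  list(seed = 1L, n_families = 8L, family_size = 40L, generation = 5L,
       alpha = 0.05, locus_marker = "WAPO-A1", target_marker = "IWB6693",
       reps_per_experiment = 12L, out_dir = NULL, phenotype_csv = NULL)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_bad("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full fine-mapping demonstration pipeline
#'
#' Simulates HIF families over the 7AL worked-example map, phenotypes
#' homozygous sister lines in two greenhouse-style experiments, classifies
#' each family by the combined blocked ANOVA, deduces the candidate interval
#' from the breakpoint constraints, classifies the reference diagnostic
#' alleles, and tabulates the reference panel frequencies. Deterministic
#' given `config$seed`; when `config$out_dir` is set, a machine-readable
#' `summary.json` plus CSV outputs are written there.
#'
#' @param config list (or YAML file path) overriding the defaults: `seed`,
#'   `n_families`, `family_size`, `generation`, `alpha`, `locus_marker`,
#'   `target_marker`, `reps_per_experiment`, `out_dir`, `phenotype_csv`
#'   (optional path to a pre-existing progeny phenotype table instead of
#'   simulating one).
#' @return the summary list, invisibly when written to disk.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_pipeline_config(), config)
  set.seed(cfg$seed)
  map <- run_stage("map", demo_map())
  region <- map$name[map$chrom == "7A"]
  locus_bp <- map$pos_bp[map$name == cfg$locus_marker]

  hif <- run_stage("simulate", {
    d <- cross_design("HIF", cfg$n_families, map, generation = cfg$generation,
                      hif = list(family_size = cfg$family_size,
                                 target = cfg$target_marker, region = region,
                                 require_breakpoint = TRUE))
    simulate_population(d)
  })

  progeny <- run_stage("finemap", {
    if (!is.null(cfg$phenotype_csv)) {
      assert_that(file.exists(cfg$phenotype_csv),
                  "phenotype file '%s' not found", cfg$phenotype_csv)
      read_phenotype_csv(cfg$phenotype_csv)
    } else {
      simulate_progeny_tests(hif, map, locus_marker = cfg$locus_marker,
                             reps = cfg$reps_per_experiment)
    }
  })

  deduction <- run_stage("finemap", {
    fams <- lapply(unique(progeny$family_id), function(fid) {
      fam <- recombinant_family(fid, hif$founders$calls[fid, region], map)
      recs <- progeny[progeny$family_id == fid, , drop = FALSE]
      list(family = fam,
           test = progeny_test_classify(recs, alpha = cfg$alpha))
    })
    list(fams = fams,
         deduction = deduce_locus_interval(
           lapply(fams, function(f)
             list(family = f$family, classification = f$test$classification))))
  })

  alleles <- run_stage("classify", {
    ref <- wapo_allele_reference()
    classify_wapo_allele(ref)
  })

  freqs <- run_stage("freq", {
    counts <- wapo_haplotype_counts()
    frequency_table(list(spring_panel = counts$spring_panel,
                         exome_hexaploid = counts$exome_hexaploid))
  })

  cand <- deduction$deduction$candidate_interval
  summary <- list(
    seed = cfg$seed,
    n_families = cfg$n_families,
    true_locus_bp = locus_bp,
    candidate_interval = list(chrom = cand$chrom, start_bp = cand$start_bp,
                              end_bp = cand$end_bp,
                              width_bp = interval_width(cand),
                              label = format_bp(interval_width(cand))),
    locus_contained = interval_contains(cand, locus_bp, open = TRUE),
    family_classifications = vapply(deduction$fams, function(f)
      f$test$classification, character(1)),
    conflicts = deduction$deduction$conflicts,
    allele_calls = setNames(alleles$allele, alleles$accession_group),
    spring_panel_percent = setNames(
      freqs$percent[freqs$group == "spring_panel"],
      freqs$allele[freqs$group == "spring_panel"]))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    write_genotype_csv(hif$founders, file.path(cfg$out_dir, "founders.csv"))
    write_phenotype_csv(progeny, file.path(cfg$out_dir, "progeny_tests.csv"))
    return(invisible(summary))
  }
  summary
}

#' Simulate progeny tests for HIF families
#'
#' For each family, homozygous sister lines (members without an `H` call at
#' the founder's heterozygous markers) are phenotyped in two experiments;
#' the sister-line class is the member's allele at the first founder-het
#' marker. Families whose founders do not segregate at the locus produce no
#' class difference beyond noise.
#'
#' @param hif a HIF population from [simulate_population()].
#' @param map the marker map.
#' @param locus_marker marker name of the true locus.
#' @param region marker names of the fine-mapping region (default: all
#'   markers on the locus chromosome); founder heterozygosity outside it
#'   (residual background segments) is ignored when selecting sister lines.
#' @param reps plants phenotyped per class and experiment.
#' @param gap homozygote phenotypic gap at the locus (trait units).
#' @param residual_sd plant-level residual SD.
#' @param experiment_effects named shifts of the two experiments.
#' @return data.frame `family_id, class, experiment, value` (plus the
#'   phenotype-table columns).
#' @export
simulate_progeny_tests <- function(hif, map, locus_marker, region = NULL,
                                   reps = 12, gap = 2.1, residual_sd = 0.9,
                                   experiment_effects = c(GH1 = 0.4, GH2 = -0.4)) {
  region <- region %||% map$name[map$chrom == map$chrom[map$name == locus_marker]]
  out <- NULL
  fam_ids <- line_ids(hif$founders)
  for (fid in fam_ids) {
    fcall <- hif$founders$calls[fid, region]
    hmk <- names(fcall)[which(fcall == "H")]
    members <- hif$pedigree$member_id[hif$pedigree$family_id == fid]
    mcalls <- hif$members$calls[members, , drop = FALSE]
    hom <- rowSums(mcalls[, hmk, drop = FALSE] == "H", na.rm = TRUE) == 0
    cls <- mcalls[, hmk[1]]
    for (klass in c("A", "B")) {
      ids <- members[hom & cls == klass]
      assert_that(length(ids) >= 1,
                  "family %s has no homozygous '%s' sister lines; increase family_size",
                  fid, klass)
      x_of <- vapply(ids, function(id)
        switch(mcalls[id, locus_marker], A = -1, B = 1, H = 0), numeric(1))
      use <- rep(seq_along(ids), length.out = reps)
      for (ex in names(experiment_effects)) {
        out <- rbind(out, data.frame(
          family_id = fid, class = klass, experiment = ex,
          line_id = ids[use],
          replicate = seq_len(reps), trait = "SNS",
          value = 18 + (gap / 2) * x_of[use] + experiment_effects[ex] +
            rnorm(reps, 0, residual_sd),
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}
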