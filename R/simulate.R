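#' Simulate gametes from diplotypes
#'
#' Meiosis model: crossovers form a Poisson process on the cM scale (Haldane,
#' no interference), so the gamete's parental phase along the ordered markers
#' of each chromosome is a two-state Markov chain whose switch probability
#' between adjacent markers at distance `d` cM is the Haldane recombination
#' fraction `(1 - exp(-d/50))/2`. The chain restricted to marker positions is
#' distributionally identical to simulating crossover counts and positions
#' explicitly, and vectorizes over gametes. The starting phase is fair.
#'
#' `simulate_gamete()` draws one gamete from one parent;
#' `simulate_gametes()` draws row `i` of the output from the parent given by
#' row `i` of `h1`/`h2`.
#'
#' @param h1,h2 parental haplotypes: 0/1 vectors over the map's markers
#'   (matrices with one row per parent for `simulate_gametes()`).
#' @param map a [marker_map()] with `pos_cM`.
#' @return integer vector (or matrix) of 0/1 gamete haplotypes.
#' @export
simulate_gamete <- function(h1, h2, map) {
  drop(simulate_gametes(rbind(h1), rbind(h2), map))
}

#' @rdname simulate_gamete
#' @export
simulate_gametes <- function(h1, h2, map) {
  assert_that(nrow(map) >= 1, "empty map rejected")
  assert_that(!is.null(map$pos_cM), "map needs pos_cM for meiosis")
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  n <- nrow(h1)
  assert_that(all(dim(h1) == dim(h2)) && ncol(h1) == nrow(map),
              "haplotypes must match the map's markers")
  out <- matrix(0L, n, nrow(map), dimnames = list(NULL, map$name))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    k <- length(idx)
    phase <- matrix(0L, n, k)
    phase[, 1] <- rbinom(n, 1L, 0.5)
    if (k > 1) {
      r <- map_recfrac(diff(map$pos_cM[idx]), "haldane")
      for (j in 2:k) {
        sw <- rbinom(n, 1L, r[j - 1])
        phase[, j] <- (phase[, j - 1] + sw) %% 2L
      }
    }
    out[, idx] <- h1[, idx, drop = FALSE] * (1L - phase) +
      h2[, idx, drop = FALSE] * phase
  }
  out
}

diplotype_calls <- function(g1, g2, map) {
  s <- g1 + g2
  m <- matrix(GENO_CODES[s + 1L], nrow(s), ncol(s),
              dimnames = list(rownames(s), map$name))
  m
}

#' Describe a biparental cross design
#'
#' @param type `"F2"`, `"RIL_self"` or `"HIF"`.
#' @param n_lines number of lines (F2/RIL) or HIF families.
#' @param map a [marker_map()] with `pos_cM`.
#' @param generation selfing generation `g` for `RIL_self` (F_g, `g >= 2`)
#'   and for the HIF source lines.
#' @param hif for `type = "HIF"`: a list with `family_size` (progeny per
#'   family), `target` (marker name that founders must be heterozygous at)
#'   and optionally `region` (marker names within which the founder's
#'   residual heterozygous calls must form a single contiguous run —
#'   the single-breakpoint founders a fine-mapping program would keep) and
#'   `require_breakpoint` (logical: keep only founders whose heterozygous
#'   run ends inside the region, i.e. screened recombinants).
#' @param seed optional integer seed applied by [simulate_population()].
#' @return a `cross_design` list.
#' @export
cross_design <- function(type = c("F2", "RIL_self", "HIF"), n_lines, map,
                         generation = 6, hif = NULL, seed = NULL) {
  type <- match.arg(type)
  assert_that(n_lines >= 1, "n_lines must be >= 1")
  assert_that(generation >= 2, "generation must be >= 2 (F2 is generation 2)")
  if (type == "HIF") {
    assert_that(!is.null(hif$family_size) && !is.null(hif$target),
                "HIF design needs hif$family_size and hif$target")
    assert_that(hif$target %in% map$name, "hif$target must be a mapped marker")
  }
  structure(list(type = type, n_lines = n_lines, map = map,
                 generation = generation, hif = hif, seed = seed),
            class = "cross_design")
}

ril_diplotypes <- function(n, map, generation) {
  M <- nrow(map)
  g1 <- simulate_gametes(matrix(0L, n, M), matrix(1L, n, M), map)
  g2 <- simulate_gametes(matrix(0L, n, M), matrix(1L, n, M), map)
  gen <- 2
  while (gen < generation) {
    new1 <- simulate_gametes(g1, g2, map)
    new2 <- simulate_gametes(g1, g2, map)
    g1 <- new1; g2 <- new2
    gen <- gen + 1
  }
  list(h1 = g1, h2 = g2)
}

single_het_run <- function(call_row, region_idx) {
  h <- which(call_row[region_idx] == "H")
  length(h) > 0 && all(diff(h) == 1)
}

#' Simulate a biparental population
#'
#' Parent 1 carries allele 0 (`A`) everywhere, parent 2 allele 1 (`B`).
#' `F2` lines are pairs of independent F1 gametes; `RIL_self` lines are the
#' product of `generation - 1` selfing rounds from the F1 (expected per-locus
#' heterozygosity `(1/2)^(g-1)` at F_g); `HIF` populations draw source RILs
#' at the requested generation, keep those heterozygous at the target marker
#' (and, when `hif$region` is given, with a single contiguous heterozygous
#' run there), and self each founder once to produce a family of sister
#' lines that segregate only inside the founder's residual heterozygous
#' segments.
#'
#' @param design a [cross_design()].
#' @return For F2/RIL: a [genotype_matrix()] with attributes `diplotypes`
#'   (list of 0/1 matrices `h1`, `h2`) and `design`. For HIF: a list with
#'   `founders` (genotype_matrix), `members` (genotype_matrix of family
#'   progeny) and `pedigree` (data.frame member_id, family_id).
#' @export
simulate_population <- function(design) {
  assert_that(inherits(design, "cross_design"), "need a cross_design")
  if (!is.null(design$seed)) set.seed(design$seed)
  map <- design$map
  n <- design$n_lines
  if (design$type == "F2") {
    dip <- ril_diplotypes(n, map, 2)
  } else if (design$type == "RIL_self") {
    dip <- ril_diplotypes(n, map, design$generation)
  } else {
    return(simulate_hif(design))
  }
  calls <- diplotype_calls(dip$h1, dip$h2, map)
  ids <- sprintf("L%04d", seq_len(n))
  gm <- genotype_matrix(calls, ids, map)
  attr(gm, "diplotypes") <- dip
  attr(gm, "design") <- design
  gm
}

simulate_hif <- function(design) {
  map <- design$map
  hif <- design$hif
  t_idx <- match(hif$target, map$name)
  region_idx <- if (!is.null(hif$region)) match(hif$region, map$name) else t_idx
  assert_that(!anyNA(region_idx), "hif$region markers must be on the map")
  need_bp <- isTRUE(hif$require_breakpoint)
  founders_h1 <- NULL; founders_h2 <- NULL
  tries <- 0
  while (is.null(founders_h1) || nrow(founders_h1) < design$n_lines) {
    tries <- tries + 1
    assert_that(tries <= 200,
                "could not find enough heterozygous founders; enlarge map or lower generation")
    batch <- max(50, design$n_lines * 2^(design$generation - 1))
    dip <- ril_diplotypes(batch, map, design$generation)
    calls <- diplotype_calls(dip$h1, dip$h2, map)
    het <- calls[, t_idx] == "H"
    ok <- het & vapply(seq_len(batch),
                       function(i) single_het_run(calls[i, ], region_idx),
                       logical(1))
    if (need_bp)  # screened recombinants: a breakpoint inside the region
      ok <- ok & rowSums(matrix(calls[, region_idx] != "H",
                                nrow(calls))) > 0
    founders_h1 <- rbind(founders_h1, dip$h1[ok, , drop = FALSE])
    founders_h2 <- rbind(founders_h2, dip$h2[ok, , drop = FALSE])
  }
  founders_h1 <- founders_h1[seq_len(design$n_lines), , drop = FALSE]
  founders_h2 <- founders_h2[seq_len(design$n_lines), , drop = FALSE]
  fam_ids <- sprintf("F%02d", seq_len(design$n_lines))
  fcalls <- diplotype_calls(founders_h1, founders_h2, map)
  founders <- genotype_matrix(fcalls, fam_ids, map)
  m <- hif$family_size
  rep_idx <- rep(seq_len(design$n_lines), each = m)
  g1 <- simulate_gametes(founders_h1[rep_idx, , drop = FALSE],
                         founders_h2[rep_idx, , drop = FALSE], map)
  g2 <- simulate_gametes(founders_h1[rep_idx, , drop = FALSE],
                         founders_h2[rep_idx, , drop = FALSE], map)
  mcalls <- diplotype_calls(g1, g2, map)
  member_ids <- sprintf("%s_%02d", fam_ids[rep_idx],
                        sequence(rep(m, design$n_lines)))
  members <- genotype_matrix(mcalls, member_ids, map)
  attr(members, "diplotypes") <- list(h1 = g1, h2 = g2)
  list(founders = founders, members = members,
       pedigree = data.frame(member_id = member_ids,
                             family_id = fam_ids[rep_idx],
                             stringsAsFactors = FALSE))
}

#' Default simulated SNS trait parameters
#'
#' Grand mean 18 spikelets; additive effect 1.05 at the main locus (so the
#' homozygote gap is 2.1 spikelets); plant-level residual SD 0.9 (the
#' progeny-test, homogeneous-background scale); optional polygenic background
#' SD 3.3 which, when switched on for RIL-level simulations, makes the RIL
#' pooled SD roughly fourfold the HIF pooled SD; two smaller background QTLs
#' (additive 0.7 and 0.5) on chromosomes 2BS and 7AS.
#'
#' @return a named list of defaults.
#' @export
sns_defaults <- function() {
  list(mu = 18, a_main = 1.05, residual_sd = 0.9, polygenic_sd = 3.3,
       background = data.frame(chrom = c("2BS", "7AS"), a = c(0.7, 0.5),
                               stringsAsFactors = FALSE))
}

#' Simulate multi-environment phenotypes
#'
#' Trait model: `value = mu + sum_q a_q x_q + d_q z_q + polygenic + env +
#' N(0, residual_sd^2)` with additive dosage `x` coded `A = -1, H = 0,
#' B = +1` and dominance indicator `z = 1` for `H`. QTLs act additively
#' across loci (no epistasis). The optional polygenic background assigns
#' each marker an effect drawn once from `N(0, polygenic_sd^2 / M)`; it
#' segregates wherever the genotypes segregate (RILs) and is essentially
#' fixed within a HIF, reproducing the variance contrast between RIL- and
#' HIF-level trials.
#'
#' @param gm a [genotype_matrix()].
#' @param qtl_effects data.frame with columns `chrom`, `pos_bp`, `a` and
#'   optionally `d`; every QTL must sit exactly at a mapped marker.
#' @param mu grand mean.
#' @param env_effects named numeric vector of environment shifts (the names
#'   become the `environment` factor).
#' @param reps_per_env replicates per line and environment.
#' @param residual_sd plant-level residual SD (> 0).
#' @param polygenic_sd SD of the genome-wide background term (0 = off).
#' @param polygenic_exclude_chrom chromosomes whose markers carry no
#'   background effects (keeps the background unlinked from a focal locus).
#' @param trait trait label.
#' @return a phenotype table: data.frame with columns `line_id`,
#'   `environment`, `replicate`, `trait`, `value`.
#' @export
simulate_phenotypes <- function(gm, qtl_effects, mu = sns_defaults()$mu,
                                env_effects = c(E1 = 0.3, E2 = -0.3),
                                reps_per_env = 1,
                                residual_sd = sns_defaults()$residual_sd,
                                polygenic_sd = 0,
                                polygenic_exclude_chrom = NULL,
                                trait = "SNS") {
  assert_that(residual_sd > 0, "residual_sd must be > 0")
  assert_that(!is.null(names(env_effects)), "env_effects must be named")
  map <- gm$map
  dos <- genotype_dosage(gm$calls)
  gval <- rep(0, nrow(dos))
  if (!is.null(qtl_effects) && nrow(qtl_effects) > 0) {
    for (q in seq_len(nrow(qtl_effects))) {
      j <- which(map$chrom == qtl_effects$chrom[q] &
                 map$pos_bp == qtl_effects$pos_bp[q])
      assert_that(length(j) == 1,
                  "QTL %s:%s is not at a mapped marker (off-map QTLs rejected)",
                  qtl_effects$chrom[q], qtl_effects$pos_bp[q])
      a <- qtl_effects$a[q]
      d <- if (!is.null(qtl_effects$d)) qtl_effects$d[q] else 0
      x <- dos[, j]
      z <- as.numeric(gm$calls[, j] == "H")
      z[is.na(z)] <- 0
      gval <- gval + a * x + d * z
    }
  }
  if (polygenic_sd > 0) {
    use <- !(map$chrom %in% (polygenic_exclude_chrom %||% character(0)))
    b <- rnorm(sum(use), 0, polygenic_sd / sqrt(sum(use)))
    gval <- gval + as.vector(dos[, use, drop = FALSE] %*% b)
  }
  ids <- line_ids(gm)
  recs <- expand.grid(line_id = ids, environment = names(env_effects),
                      replicate = seq_len(reps_per_env),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  recs$trait <- trait
  recs$value <- mu + gval[match(recs$line_id, ids)] +
    env_effects[recs$environment] +
    rnorm(nrow(recs), 0, residual_sd)
  rownames(recs) <- NULL
  recs[, c("line_id", "environment", "replicate", "trait", "value")]
}

# additive dosage coding A=-1, H=0, B=+1; missing contributes 0
genotype_dosage <- function(calls) {
  d <- matrix(0, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  d[calls == "A"] <- -1
  d[calls == "B"] <- 1
  d
}

#' Realized line-mean heritability
#'
#' One-way lines ANOVA on a (balanced) phenotype table:
#' `var_G = (MS_line - MS_resid) / r` with `r` records per line, and
#' `H^2 = var_G / (var_G + MS_resid / r)` on the line-mean basis.
#'
#' @param pheno a phenotype table (one trait).
#' @return list with `H2`, `var_g`, `var_e` (residual variance), `r`.
#' @export
realized_heritability <- function(pheno) {
  assert_that(length(unique(pheno$trait)) == 1,
              "supply a single trait at a time")
  fit <- lm(value ~ factor(line_id), data = pheno)
  an <- anova(fit)
  ms_line <- an$`Mean Sq`[1]; ms_err <- an$`Mean Sq`[2]
  r <- nrow(pheno) / length(unique(pheno$line_id))
  var_g <- max(0, (ms_line - ms_err) / r)
  list(H2 = var_g / (var_g + ms_err / r), var_g = var_g, var_e = ms_err, r = r)
}
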