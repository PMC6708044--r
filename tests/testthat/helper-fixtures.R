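# fixtures are built in code; no binary data ships with the package

# evenly spaced single-chromosome map
tiny_map <- function(n = 11, chrom = "1A", spacing_cM = 10, bp_per_cM = 1e6,
                     map_function = "haldane") {
  marker_map(sprintf("%s_m%02d", chrom, seq_len(n)),
             rep(chrom, n),
             pos_bp = 1 + (seq_len(n) - 1) * spacing_cM * bp_per_cM,
             pos_cM = (seq_len(n) - 1) * spacing_cM,
             map_function = map_function)
}

# several chromosomes glued together
multi_map <- function(chroms = c("1A", "2B", "3D"), n = 11, spacing_cM = 10) {
  maps <- lapply(chroms, function(ch) as.data.frame(tiny_map(n, ch, spacing_cM)))
  d <- do.call(rbind, maps)
  marker_map(d$name, d$chrom, d$pos_bp, d$pos_cM, map_function = "haldane")
}

# genotype matrix from a character vector of row strings like "AAHBB"
gm_from_strings <- function(rows, map, ids = sprintf("L%02d", seq_along(rows))) {
  m <- do.call(rbind, strsplit(rows, ""))
  m[m == "-"] <- NA_character_
  colnames(m) <- map$name
  genotype_matrix(m, ids, map)
}

# line means of a phenotype table, as a named vector for hk_scan()
line_means <- function(pheno) {
  tapply(pheno$value, pheno$line_id, mean)
}

# brute-force locus deduction over elementary marker gaps (oracle):
# a gap between adjacent markers is feasible iff it lies inside every
# heterozygous family's maximal segment and outside every homozygous
# family's minimal-segment exclusion; adjacent feasible gaps are merged
# unless their shared marker position is itself excluded
oracle_deduce <- function(families, map_pos) {
  gaps <- cbind(map_pos[-length(map_pos)], map_pos[-1])
  feasible <- rep(TRUE, nrow(gaps))
  excl <- list()
  for (f in families) {
    hm <- f$family$het_max; hmin <- f$family$het_min
    if (f$classification == "heterozygous") {
      feasible <- feasible & gaps[, 1] >= hm$start_bp & gaps[, 2] <= hm$end_bp
    } else if (!is.null(hmin)) {
      feasible <- feasible & (gaps[, 2] <= hmin$start_bp | gaps[, 1] >= hmin$end_bp)
      excl <- c(excl, list(c(hmin$start_bp, hmin$end_bp)))
    }
  }
  if (!any(feasible)) return(NULL)
  point_excluded <- function(p) any(vapply(excl, function(e)
    p >= e[1] && p <= e[2], logical(1)))
  # walk gaps, breaking runs at excluded shared marker positions
  best <- NULL; bw <- -1
  i <- 1
  while (i <= nrow(gaps)) {
    if (!feasible[i]) { i <- i + 1; next }
    j <- i
    while (j < nrow(gaps) && feasible[j + 1] && !point_excluded(gaps[j, 2]))
      j <- j + 1
    iv <- c(gaps[i, 1], gaps[j, 2])
    if (iv[2] - iv[1] > bw) { bw <- iv[2] - iv[1]; best <- iv }
    i <- j + 1
  }
  best
}

# random single-H-run founder call vector over `n` markers
random_founder_calls <- function(n, map) {
  s <- sample.int(n - 1, 1)
  e <- sample(s:min(n, s + sample.int(4, 1)), 1)
  left <- sample(c("A", "B"), 1); right <- sample(c("A", "B"), 1)
  calls <- c(rep(left, s - 1), rep("H", e - s + 1), rep(right, n - e))
  names(calls) <- map$name
  calls
}
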