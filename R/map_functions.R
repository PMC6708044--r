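#' Genetic map functions
#'
#' Conversions between recombination fraction and map distance in cM under
#' the Kosambi (partial interference) or Haldane (no interference) mapping
#' function. Kosambi is the default throughout the package (the convention of
#' wheat linkage maps); Haldane is the model under which the meiosis
#' simulator operates (Poisson crossovers, no interference).
#'
#' * Kosambi: `d = 25 * log((1 + 2r) / (1 - 2r))`, inverse `r = tanh(d/50)/2`.
#' * Haldane: `d = -50 * log(1 - 2r)`, inverse `r = (1 - exp(-d/50))/2`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d_cM map distance(s) in centiMorgans, `>= 0`.
#' @param kind `"kosambi"` or `"haldane"`.
#' @return numeric vector (cM for `map_distance`, recombination fraction for
#'   `map_recfrac`).
#' @examples
#' map_distance(0.25, "haldane")           # -50*log(0.5)
#' map_recfrac(map_distance(0.1), )        # 0.1 (round trip)
#' @rdname map_functions
#' @export
map_distance <- function(r, kind = c("kosambi", "haldane")) {
  kind <- match.arg(kind)
  assert_that(all(r >= 0 & r < 0.5), "recombination fractions must lie in [0, 0.5)")
  switch(kind,
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)),
         haldane = -50 * log(1 - 2 * r))
}

#' @rdname map_functions
#' @export
map_recfrac <- function(d_cM, kind = c("kosambi", "haldane")) {
  kind <- match.arg(kind)
  assert_that(all(d_cM >= 0), "map distances must be >= 0")
  switch(kind,
         kosambi = tanh(d_cM / 50) / 2,
         haldane = (1 - exp(-d_cM / 50)) / 2)
}

#' Expanded recombination fraction for selfed RILs
#'
#' Repeated selfing accumulates recombination: the fraction of recombinant
#' RIL genotypes between two loci with per-meiosis recombination fraction `r`
#' is `R = 2r / (1 + 2r)` at fixation.
#'
#' @param r per-meiosis recombination fraction in `[0, 0.5)`.
#' @return expanded fraction `R` in `[0, 0.5)`.
#' @examples
#' ril_expansion(0.25)  # 1/3
#' @export
ril_expansion <- function(r) {
  assert_that(all(r >= 0 & r < 0.5), "recombination fractions must lie in [0, 0.5)")
  2 * r / (1 + 2 * r)
}

#' Calibrate the cM-per-Mb scalar from an observed screening fraction
#'
#' Recombinant screens report the fraction of plants (not gametes) showing a
#' recombination event between two flanking markers. For an F2-type screen of
#' plants from a heterozygous parent, a plant is recombinant when either of
#' its two independent gametes recombined, so the plant-level fraction is
#' `p = 1 - (1 - r)^2`. Given the physical window size and the observed
#' fraction, this returns the cM/Mb scalar that reproduces it, which the
#' simulator and [plan_rescreen()] use to turn physical windows into expected
#' recombinant yields.
#'
#' @param window_bp physical size of the screened window in bp.
#' @param observed_fraction observed fraction of recombinant plants.
#' @param screen `"F2_plants"` (two informative meioses per plant) or
#'   `"gametes"` (one).
#' @param kind map function used to convert `r` to cM.
#' @return cM per Mb (numeric scalar).
#' @examples
#' # 74 recombinants among 617 plants over a 9.13-Mb window
#' calibrate_cm_per_mb(9129458, 74 / 617)
#' @export
calibrate_cm_per_mb <- function(window_bp, observed_fraction,
                                screen = c("F2_plants", "gametes"),
                                kind = c("kosambi", "haldane")) {
  screen <- match.arg(screen)
  kind <- match.arg(kind)
  assert_that(window_bp > 0, "window must have positive size")
  assert_that(observed_fraction > 0 && observed_fraction < 1,
              "observed fraction must be in (0,1)")
  r <- switch(screen,
              F2_plants = 1 - sqrt(1 - observed_fraction),
              gametes = observed_fraction)
  assert_that(r < 0.5, "implied recombination fraction >= 0.5")
  map_distance(r, kind) / (window_bp / 1e6)
}

#' Expected recombinant fraction across a physical window
#'
#' Inverse companion of [calibrate_cm_per_mb()].
#'
#' @param window_bp window size in bp.
#' @param cm_per_mb calibrated scalar.
#' @inheritParams calibrate_cm_per_mb
#' @return expected fraction of recombinant individuals.
#' @export
expected_recombinant_fraction <- function(window_bp, cm_per_mb,
                                          screen = c("F2_plants", "gametes"),
                                          kind = c("kosambi", "haldane")) {
  screen <- match.arg(screen)
  kind <- match.arg(kind)
  r <- map_recfrac(cm_per_mb * window_bp / 1e6, kind)
  switch(screen, F2_plants = 1 - (1 - r)^2, gametes = r)
}
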