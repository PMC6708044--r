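`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going up, the convention used
#' for printed interval sizes (kb as integers, Mb to one decimal) and for
#' percentage tables. R's `round()` rounds halves to even, which does not
#' reproduce printed values such as 83.2%.
#'
#' @param x numeric vector (non-negative values expected for widths).
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(87.136)   # 87
#' round_half_up(0.5)      # 1 (round() would give 0)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_bad(...)
  invisible(TRUE)
}
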