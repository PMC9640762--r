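#' Round half away from zero
#'
#' Commercial rounding used for all whole-percent readiness tables:
#' \code{round_half_up(88.5)} is 89, unlike base \code{round()}'s
#' round-half-to-even. A tiny epsilon guards values such as 100*23/26 that
#' land a hair under .5 in binary floating point only when they were not
#' meant to.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Whole-percent share with the package rounding rule
#' @param k numerator count.
#' @param n denominator count.
#' @return integer percentage, \code{round_half_up(100 * k / n)}.
#' @keywords internal
pct <- function(k, n) round_half_up(100 * k / n)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ra <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "removalaccess_error")))
}

warn_ra <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "removalaccess_warning")))
}
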