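#' Likely near-term future status
#'
#' Projects present status five years ahead by scaling it with the trend
#' and pressure-resilience scores:
#' `x_F = (1 + beta * T + (1 - beta) * PR) * x`.
#' `beta` sets the relative importance of the directly measured trend
#' versus the indirectly inferred PR score; the default 0.67 used
#' throughout the package weights them 2:1. Because `T` and `PR` both lie
#' in `[-1, 1]` the multiplier lies in `[0, 2]`: the projection can never
#' go negative, but it can exceed the reference-point ceiling, in which
#' case it is clamped to 1 (use `clamp = FALSE` to obtain the raw value).
#'
#' @param x Present status in `[0, 1]`; `NA` propagates.
#' @param T Trend score in `[-1, 1]`.
#' @param PR Pressure-resilience score in `[-1, 1]`.
#' @param beta Trend weight in `[0, 1]`.
#' @param clamp Clamp the result to `[0, 1]` (default `TRUE`).
#' @return Projected status (vectorized).
#' @export
#' @examples
#' future_status(0.5, T = 1, PR = 1, beta = 0.67) # at the clamp boundary
future_status <- function(x, T, PR, beta = 0.67, clamp = TRUE) {
  stopifnot(is.numeric(beta), all(beta >= 0 & beta <= 1))
  raw <- (1 + beta * T + (1 - beta) * PR) * x
  if (clamp) pmin(1, pmax(0, raw)) else raw
}

#' Service score
#'
#' The service score is the mean of the present and likely near-term
#' future status, `I = (x + x_F) / 2`, reported on a 0-100 scale by
#' default (the unit-scale ratio multiplied by 100).
#'
#' @param x,x_F Present and future status in `[0, 1]`; `NA` propagates.
#' @param report_scale `"percent100"` (default) or `"unit"`.
#' @return Service score(s) on the requested scale.
#' @export
#' @examples
#' service_score(0.6, 0.4)
service_score <- function(x, x_F, report_scale = c("percent100", "unit")) {
  report_scale <- match.arg(report_scale)
  out <- (x + x_F) / 2
  if (report_scale == "percent100") out <- out * 100
  out
}

#' Sustainability score
#'
#' The relative change from present to likely near-term future status,
#' `S = (x_F - x) / x`, stored as a fraction (0.2 means +20%). A positive
#' score means the service is expected to improve under present
#' conditions; a negative score means it will decay, and the environmental
#' factors behind the decay can be read off the factor scores. When the
#' present status is 0 the ratio is undefined and `NA` is returned
#' (reported as a dash).
#'
#' @param x,x_F Present and future status in `[0, 1]`.
#' @return Sustainability fraction(s), `NA` where `x` is 0.
#' @export
#' @examples
#' sustainability(0.5, 0.6) # +20%
sustainability <- function(x, x_F) {
  out <- (x_F - x) / x
  out[!is.na(x) & x == 0] <- NA_real_
  out
}
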