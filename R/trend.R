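#' Fit the five-year trend score
#'
#' The trend score summarizes whether a service's normalized status moved
#' up or down over the assessment window. An ordinary least-squares line is
#' fit to the (year, status) points; the trend score is five times the
#' per-year slope, `T = 5 t`, clamped to `[-1, +1]` (a slope sustained over
#' the five-year window maps onto the score range). Its 95% confidence
#' interval is `5 t +/- 15 se`, where `se` is the standard error of the
#' slope: the half-width multiplies the standard error by 3 (an
#' approximation to the two-tailed t quantile at three residual degrees of
#' freedom) and then by the same factor of 5 that scales the slope. Bounds
#' falling outside `[-1, 1]` are clamped and flagged.
#'
#' With fewer than `min_points` usable points the trend cannot be estimated
#' and is set to 0 with flag `NO_TREND_DATA` and a degenerate (0, 0)
#' interval, matching the missing-data rule of the scoring framework.
#'
#' @param years Calendar years (distinct).
#' @param x Normalized status values for those years; `NA` pairs are
#'   dropped.
#' @param min_points Minimum usable points for a fit (default 3; the slope
#'   standard error is undefined below 3).
#' @return A list with `T` (clamped trend score), `slope` (per-year OLS
#'   slope), `se` (standard error of the slope), `T_lower`, `T_upper`
#'   (clamped 95% bounds), `n_points`, `clamped` (logical, score or bounds),
#'   and `flags`.
#' @export
#' @examples
#' fit_trend(2009:2013, c(0.10, 0.12, 0.14, 0.16, 0.18))$T
fit_trend <- function(years, x, min_points = 3) {
  stopifnot(length(years) == length(x))
  keep <- !is.na(years) & !is.na(x)
  years <- as.numeric(years[keep])
  x <- as.numeric(x[keep])
  n <- length(x)
  no_trend <- list(T = 0, slope = NA_real_, se = NA_real_,
                   T_lower = 0, T_upper = 0, n_points = n,
                   clamped = FALSE, flags = "NO_TREND_DATA")
  if (n < min_points) return(no_trend)
  if (length(unique(years)) == 1) {
    abort("DEGENERATE_ABSCISSA: all trend years identical",
          class = "cei_trend_error")
  }
  fit <- lm(x ~ years)
  t_hat <- unname(coef(fit)[2])
  # suppressed warning: summary.lm complains about essentially perfect fits,
  # which are routine here (noise-free or constant series)
  se <- unname(suppressWarnings(summary(fit))$coefficients["years", "Std. Error"])
  if (!is.finite(se)) se <- NA_real_

  flags <- character()
  T_raw <- 5 * t_hat
  T_score <- max(-1, min(1, T_raw))
  clamped <- FALSE
  if (T_score != T_raw) {
    clamped <- TRUE
    flags <- c(flags, "CLAMPED_TREND")
  }
  hw <- if (is.na(se)) NA_real_ else trend_ci_halfwidth(se)
  up_raw <- T_raw + hw
  lo_raw <- T_raw - hw
  T_upper <- max(-1, min(1, up_raw))
  T_lower <- max(-1, min(1, lo_raw))
  if (!is.na(up_raw) && (T_upper != up_raw || T_lower != lo_raw)) {
    clamped <- TRUE
    flags <- c(flags, "CLAMPED_TREND_CI")
  }
  list(T = T_score, slope = t_hat, se = se,
       T_lower = T_lower, T_upper = T_upper,
       n_points = n, clamped = clamped, flags = flags)
}

#' Half-width of the trend-score confidence interval
#'
#' Returns `15 * se`: the slope standard error scaled by 3 (the
#' approximate 95% two-tailed t multiplier at three degrees of freedom,
#' appropriate for a five-point yearly fit) and by 5 (the factor mapping a
#' per-year slope onto the trend-score range).
#'
#' @param se Standard error of the per-year slope (non-negative).
#' @return The half-width applied around `5 t`.
#' @export
#' @examples
#' trend_ci_halfwidth(0.01)
trend_ci_halfwidth <- function(se) {
  stopifnot(is.numeric(se))
  if (any(se < 0, na.rm = TRUE)) {
    abort("`se` must be non-negative", class = "cei_trend_error")
  }
  5 * 3 * se
}
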