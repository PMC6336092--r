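#' Screen outlying indicator values
#'
#' Applies the outlier rule to the pooled per-service sample (all sites by
#' all window years): any value more than `k` sample standard deviations
#' from the pooled mean is excluded from the calculations. Screening is
#' single-pass: the mean and standard deviation are computed once, on the
#' full pooled sample, and are not re-estimated after exclusion. With fewer
#' than two values, or when all values are equal (zero standard deviation),
#' nothing is excluded.
#'
#' @param obs A data frame with at least a `value` column; typically also
#'   `site_id` and `year`. Rows with `NA` values are dropped.
#' @param k Exclusion multiplier (default 2, i.e. the 2-sigma rule).
#' @return A list with `retained` and `excluded` (row subsets of `obs`),
#'   `mean`, `sd` (sample standard deviation, n-1 denominator), and
#'   `flags` (`"NO_SCREENING"` when fewer than two values were available).
#' @export
#' @examples
#' screen_outliers(data.frame(value = c(rep(1, 19), 10)))$excluded
screen_outliers <- function(obs, k = 2) {
  stopifnot(is.data.frame(obs), "value" %in% names(obs))
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    abort("`k` must be a single positive number", class = "cei_status_error")
  }
  obs <- obs[!is.na(obs$value), , drop = FALSE]
  n <- nrow(obs)
  if (n < 2) {
    return(list(retained = obs, excluded = obs[0, , drop = FALSE],
                mean = if (n > 0) mean(obs$value) else NA_real_,
                sd = NA_real_, flags = "NO_SCREENING"))
  }
  m <- mean(obs$value)
  s <- sd(obs$value)
  out <- if (s > 0) abs(obs$value - m) > k * s else rep(FALSE, n)
  list(
    retained = obs[!out, , drop = FALSE],
    excluded = obs[out, , drop = FALSE],
    mean = m, sd = s, flags = character()
  )
}

#' Select the reference point for a service
#'
#' The reference point is the normalization ceiling for present status: the
#' maximum retained (non-outlier) indicator value across all sites and all
#' window years for the service. Scoring against a cross-site maximum makes
#' the assessment a relative comparison among the sites rather than a
#' comparison against an absolute "best" condition. Ties are broken by the
#' earliest year, then the lexicographically smallest site id, so the
#' recorded provenance is reproducible. A fixed user-supplied ceiling can
#' override the observed maximum (e.g. an ideal pre-deterioration value in
#' degraded waters).
#'
#' @param retained Retained observations for one service: a data frame with
#'   `site_id`, `year`, `value` (as returned by [screen_outliers()]).
#' @param service_id Service identifier, used for provenance and messages.
#' @param fixed Optional fixed positive reference value overriding the
#'   observed maximum.
#' @return A list with `service_id`, `X_R`, `source_site`, `source_year`
#'   (both `NA` when `fixed` is used) and `fixed` (logical).
#' @section Errors: If no retained observation is positive the reference
#'   point is undefined and an error of class `cei_reference_undefined` is
#'   raised (normalization is impossible).
#' @export
reference_point <- function(retained, service_id = NA_character_, fixed = NULL) {
  if (!is.null(fixed)) {
    stopifnot(is.numeric(fixed), length(fixed) == 1, fixed > 0)
    return(list(service_id = service_id, X_R = as.numeric(fixed),
                source_site = NA_character_, source_year = NA_integer_,
                fixed = TRUE))
  }
  stopifnot(is.data.frame(retained))
  vals <- retained$value
  if (nrow(retained) == 0 || all(is.na(vals)) || max(vals, na.rm = TRUE) <= 0) {
    abort(sprintf("REFERENCE_UNDEFINED: no positive retained value for service '%s'",
                  service_id),
          class = "cei_reference_undefined")
  }
  x_max <- max(vals, na.rm = TRUE)
  at <- retained[!is.na(vals) & vals == x_max, , drop = FALSE]
  at <- at[order(at$year, at$site_id), , drop = FALSE]
  list(
    service_id = service_id,
    X_R = x_max,
    source_site = as.character(at$site_id[1]),
    source_year = as.integer(at$year[1]),
    fixed = FALSE
  )
}

#' Normalize present status against the reference point
#'
#' Present status is the ratio of the current indicator value to the
#' reference point, `x = X / X_R`. For retained evaluation-year values the
#' ratio lies in `[0, 1]` by construction of the reference point over the
#' same pooled sample; a value that was itself screened out as an outlier
#' is still normalized (and flagged upstream) and may exceed 1.
#'
#' @param X Indicator value(s); `NA` propagates.
#' @param ref Reference point: either the numeric `X_R` or the list
#'   returned by [reference_point()].
#' @return Numeric vector of normalized status values.
#' @export
#' @examples
#' present_status(1.7, 3.4)
present_status <- function(X, ref) {
  X_R <- if (is.list(ref)) ref$X_R else ref
  stopifnot(is.numeric(X_R), length(X_R) == 1)
  if (!is.finite(X_R) || X_R <= 0) {
    abort("reference point must be positive", class = "cei_status_error")
  }
  as.numeric(X) / X_R
}
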