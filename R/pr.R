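#' Score a quantitative environmental factor
#'
#' Evaluates the piecewise-linear pressure-resilience model of a
#' quantitative factor. For `direction = "increasing_good"` the score is
#' -1 at or below `lo_threshold`, +1 at or above `hi_threshold`, and
#' linear in between; negative scores mark the factor as a pressure and
#' positive scores as a resilience. The canonical example is dissolved
#' oxygen with thresholds 2 and 6 mg/L: hypoxic water at 2 mg/L scores
#' -1, well-oxygenated water at 6 mg/L scores +1, and the pressure /
#' resilience boundary sits at the 4 mg/L midpoint. For
#' `direction = "decreasing_good"` the model is mirrored (score -1 at or
#' above `hi_threshold`, +1 at or below `lo_threshold`).
#'
#' @param value Measured value(s) of the factor; `NA` propagates.
#' @param f A quantitative [factor_definition()] (one-row data frame or
#'   equivalent list).
#' @return Numeric score(s) in `[-1, 1]`.
#' @export
#' @examples
#' do_model <- factor_definition("anoxic_water", "food",
#'   kind = "quantitative", lo_threshold = 2, hi_threshold = 6
#' )
#' quantitative_factor_score(c(2, 3, 4, 6), do_model)
quantitative_factor_score <- function(value, f) {
  f <- .as_factor_row(f)
  if (f$kind != "quantitative") {
    abort(sprintf("factor '%s' is not quantitative", f$factor_id),
          class = "cei_pr_error")
  }
  lo <- f$lo_threshold
  hi <- f$hi_threshold
  raw <- -1 + 2 * (as.numeric(value) - lo) / (hi - lo)
  s <- pmin(1, pmax(-1, raw))
  if (identical(f$direction, "decreasing_good")) s <- -s
  s
}

#' Score a qualitative environmental factor
#'
#' Presence/absence factors (e.g. blue-tide occurrence, ground stability,
#' existence of a nearby source of juveniles) cannot be graded on a
#' continuous scale, so an observed favorable condition scores
#' `+qualitative_magnitude` and an observed unfavorable condition scores
#' `-qualitative_magnitude` (default 0.5, i.e. half the influence of a
#' factor scored from measurements). An `unknown` state yields `NA` and is
#' excluded from PR aggregation rather than being treated as neutral.
#'
#' @param state `"positive"`, `"negative"`, or `"unknown"` (vectorized).
#' @param f A qualitative [factor_definition()].
#' @return Numeric score(s): plus/minus the factor magnitude, or `NA`.
#' @export
#' @examples
#' bt <- factor_definition("blue_tide", "food", kind = "qualitative")
#' qualitative_factor_score(c("positive", "negative", "unknown"), bt)
qualitative_factor_score <- function(state, f) {
  f <- .as_factor_row(f)
  if (f$kind != "qualitative") {
    abort(sprintf("factor '%s' is not qualitative", f$factor_id),
          class = "cei_pr_error")
  }
  state <- as.character(state)
  .check_enum(state, .factor_states, "factor state")
  m <- f$qualitative_magnitude
  out <- rep(NA_real_, length(state))
  out[state == "positive"] <- m
  out[state == "negative"] <- -m
  out
}

#' Aggregate factor scores into a service PR score
#'
#' The service-level pressure-resilience score is the weighted arithmetic
#' mean of the non-`NA` factor scores (weights default to 1, i.e. equal
#' influence of every factor). If no factor could be scored the PR score
#' is `NA`; downstream the future-status projection then falls back to
#' PR = 0 (flagged), so the projection reflects the trend alone.
#'
#' @param scores Numeric factor scores in `[-1, 1]`, `NA` allowed.
#' @param weights Optional positive weights, recycled against `scores`.
#' @return A single score in `[-1, 1]`, or `NA` if nothing was scored.
#' @export
#' @examples
#' aggregate_pr(c(-1, -0.5, 0.5, -0.5, 0.5))
aggregate_pr <- function(scores, weights = NULL) {
  scores <- as.numeric(scores)
  if (is.null(weights)) weights <- rep(1, length(scores))
  stopifnot(length(weights) == length(scores), all(weights > 0, na.rm = TRUE))
  ok <- !is.na(scores)
  if (!any(ok)) return(NA_real_)
  sum(scores[ok] * weights[ok]) / sum(weights[ok])
}

#' Identify factors needing countermeasures
#'
#' The machine-readable form of the per-service factor radar chart: factors
#' whose score falls below `threshold` (default 0, i.e. factors acting as
#' pressures) are listed in ascending score order -- worst first -- with
#' lexicographic factor-id order breaking ties.
#'
#' @param scores A data frame with columns `factor_id` and `score`.
#' @param threshold Scores strictly below this are flagged. Default 0.
#' @return Character vector of factor ids, possibly empty.
#' @export
#' @examples
#' factor_diagnostics(data.frame(
#'   factor_id = c("anoxic_water", "blue_tide", "source_of_juveniles"),
#'   score = c(-1, -0.5, 0.5)
#' ))
factor_diagnostics <- function(scores, threshold = 0) {
  stopifnot(is.data.frame(scores),
            all(c("factor_id", "score") %in% names(scores)))
  bad <- scores[!is.na(scores$score) & scores$score < threshold, , drop = FALSE]
  bad <- bad[order(bad$score, bad$factor_id), , drop = FALSE]
  as.character(bad$factor_id)
}

.as_factor_row <- function(f) {
  if (is.data.frame(f)) {
    if (nrow(f) != 1) {
      abort("expected a single factor definition", class = "cei_pr_error")
    }
    f <- as.list(f)
  }
  stopifnot(is.list(f), !is.null(f$kind))
  f
}
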