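# Enumerations shared by the configuration schema.
.report_scales <- c("percent100", "unit")
.spatial_bases <- c("per_unit_area", "whole_site")
.temporal_statistics <- c("annual_mean", "annual_total", "annual_max", "annual_min")
.factor_kinds <- c("quantitative", "qualitative")
.factor_directions <- c("increasing_good", "decreasing_good")
.site_types <- c("natural", "artificial")
.factor_states <- c("positive", "negative", "unknown")

#' Build an assessment configuration
#'
#' An assessment configuration declares the sites being compared, the
#' services (and sub-services) being scored, the conceptual model mapping
#' each service to its environmental factors, and the global scoring
#' parameters.
#'
#' @param evaluation_year Calendar year being assessed. The trend window is
#'   the `window_years` most recent years ending at (and including) this
#'   year.
#' @param sites Site declarations: a data frame (or list of lists) with
#'   columns `site_id` (required, unique), `name`, `natural_or_artificial`
#'   (`"natural"` or `"artificial"`), `area_m2`, `coastline_m`. Area and
#'   coastline are descriptive metadata only.
#' @param services Service declarations: `service_id` (required, unique),
#'   `name`, `index_description`, `spatial_basis` (`"per_unit_area"` or
#'   `"whole_site"`), `temporal_statistic` (`"annual_mean"`,
#'   `"annual_total"`, `"annual_max"`, `"annual_min"`), `unit`. The spatial
#'   basis and temporal statistic document the convention under which the
#'   indicator values were computed; the scoring itself is agnostic to them.
#' @param factors Conceptual-model factor declarations; see
#'   [factor_definition()]. Each factor must reference a declared service.
#'   May be `NULL` when no pressure-resilience scoring is wanted.
#' @param window_years Number of most-recent years (including the
#'   evaluation year) pooled for the reference point and the trend fit.
#'   Default 5.
#' @param beta Relative weight of the trend versus the pressure-resilience
#'   score in the near-term projection, in `[0, 1]`. The default 0.67
#'   weights the directly measured trend 2:1 over the indirectly measured
#'   PR score.
#' @param outlier_k Outlier screening multiplier: pooled values more than
#'   `outlier_k` sample standard deviations from the pooled mean are
#'   excluded from the calculations. Default 2.
#' @param report_scale `"percent100"` (service scores on 0-100, the usual
#'   reporting convention) or `"unit"` (0-1).
#' @param min_trend_points Minimum number of retained yearly values needed
#'   to fit a trend; below it the trend is set to 0 and flagged. Default 3.
#' @param pr_years `"evaluation"` (default) scores factors from their
#'   evaluation-year state only; `"window"` averages factor scores over the
#'   whole window.
#' @param reference_points Optional named list of fixed, user-supplied
#'   reference points (`service_id = value`), overriding the observed
#'   cross-site maximum. Intended for degraded waters where an ideal
#'   historical value is a better normalization ceiling than any current
#'   observation.
#'
#' @return A `cei_config` object: a validated list with normalized tibbles
#'   `sites`, `services`, `factors` and the scalar parameters above.
#' @seealso [read_cei_config()], [validate_config()], [score_assessment()]
#' @export
#' @examples
#' cfg <- cei_config(
#'   evaluation_year = 2013,
#'   sites = data.frame(site_id = c("A", "B")),
#'   services = data.frame(service_id = "food"),
#'   factors = factor_definition("anoxic_water", "food",
#'     kind = "quantitative", lo_threshold = 2, hi_threshold = 6
#'   )
#' )
#' cfg$beta
cei_config <- function(evaluation_year,
                       sites,
                       services,
                       factors = NULL,
                       window_years = 5L,
                       beta = 0.67,
                       outlier_k = 2,
                       report_scale = c("percent100", "unit"),
                       min_trend_points = 3L,
                       pr_years = c("evaluation", "window"),
                       reference_points = NULL) {
  report_scale <- match.arg(report_scale)
  pr_years <- match.arg(pr_years)
  .check_scalar_number(evaluation_year, "evaluation_year")
  .check_scalar_number(window_years, "window_years")
  .check_scalar_number(beta, "beta")
  .check_scalar_number(outlier_k, "outlier_k")
  .check_scalar_number(min_trend_points, "min_trend_points")
  if (window_years < 2) {
    abort("`window_years` must be at least 2", class = "cei_config_error")
  }
  if (beta < 0 || beta > 1) {
    abort(sprintf("`beta` must lie in [0, 1], got %g", beta),
          class = "cei_config_error")
  }
  if (outlier_k <= 0) {
    abort("`outlier_k` must be positive", class = "cei_config_error")
  }
  if (min_trend_points < 1) {
    abort("`min_trend_points` must be at least 1", class = "cei_config_error")
  }

  sites <- .as_sites(sites)
  services <- .as_services(services)
  factors <- .as_factors(factors)

  missing_svc <- setdiff(factors$service_id, services$service_id)
  if (length(missing_svc) > 0) {
    bad <- factors$factor_id[match(missing_svc[1], factors$service_id)]
    abort(sprintf("factor '%s' references undeclared service '%s'",
                  bad, missing_svc[1]),
          class = "cei_config_error")
  }

  if (!is.null(reference_points)) {
    reference_points <- as.list(reference_points)
    if (is.null(names(reference_points)) || any(names(reference_points) == "")) {
      abort("`reference_points` must be a named list of service_id = value",
            class = "cei_config_error")
    }
    unknown <- setdiff(names(reference_points), services$service_id)
    if (length(unknown) > 0) {
      abort(sprintf("reference point supplied for undeclared service '%s'",
                    unknown[1]),
            class = "cei_config_error")
    }
    reference_points <- lapply(reference_points, function(v) {
      v <- as.numeric(v)
      if (length(v) != 1 || !is.finite(v) || v <= 0) {
        abort("fixed reference points must be single positive numbers",
              class = "cei_config_error")
      }
      v
    })
  }

  structure(
    list(
      evaluation_year = as.integer(evaluation_year),
      window_years = as.integer(window_years),
      beta = as.numeric(beta),
      outlier_k = as.numeric(outlier_k),
      report_scale = report_scale,
      min_trend_points = as.integer(min_trend_points),
      pr_years = pr_years,
      sites = sites,
      services = services,
      factors = factors,
      reference_points = reference_points
    ),
    class = "cei_config"
  )
}

#' Declare an environmental factor of the conceptual model
#'
#' A factor is either *quantitative* (a measured quantity scored on a
#' piecewise-linear model between two thresholds) or *qualitative* (a
#' presence/absence condition scored as plus or minus a fixed magnitude).
#' For a quantitative factor with `direction = "increasing_good"` the score
#' is -1 at or below `lo_threshold` (full pressure), +1 at or above
#' `hi_threshold` (full resilience), and linear in between; for example a
#' dissolved-oxygen factor with thresholds 2 and 6 mg/L scores -1 at
#' 2 mg/L, +1 at 6 mg/L, and 0 at 4 mg/L. `direction = "decreasing_good"`
#' mirrors the model for quantities where smaller values are favorable.
#'
#' Qualitative factors default to magnitude 0.5: where a condition can only
#' be judged present/absent, its influence is assumed half that of a factor
#' scored from measurements. The magnitude is configurable per factor.
#'
#' @param factor_id,service_id Identifiers; the factor applies to the named
#'   service.
#' @param kind `"quantitative"` or `"qualitative"`.
#' @param lo_threshold,hi_threshold Quantitative only: the values at which
#'   the score saturates; `lo_threshold < hi_threshold`.
#' @param direction Quantitative only: `"increasing_good"` (default) or
#'   `"decreasing_good"`.
#' @param qualitative_magnitude Qualitative only: score magnitude in
#'   `(0, 1]`, default 0.5.
#' @param weight Relative factor weight in the PR average; default 1
#'   (equal weights).
#' @param description Free text.
#' @return A one-row tibble suitable for the `factors` argument of
#'   [cei_config()]; rows may be combined with `rbind()`.
#' @export
#' @examples
#' rbind(
#'   factor_definition("anoxic_water", "food",
#'     kind = "quantitative", lo_threshold = 2, hi_threshold = 6
#'   ),
#'   factor_definition("blue_tide", "food", kind = "qualitative")
#' )
factor_definition <- function(factor_id, service_id,
                              kind = c("quantitative", "qualitative"),
                              lo_threshold = NULL, hi_threshold = NULL,
                              direction = c("increasing_good", "decreasing_good"),
                              qualitative_magnitude = 0.5,
                              weight = 1,
                              description = NA_character_) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  .as_factors(tibble(
    factor_id = as.character(factor_id),
    service_id = as.character(service_id),
    kind = kind,
    lo_threshold = as.numeric(lo_threshold %||% NA_real_),
    hi_threshold = as.numeric(hi_threshold %||% NA_real_),
    direction = direction,
    qualitative_magnitude = as.numeric(qualitative_magnitude),
    weight = as.numeric(weight),
    description = as.character(description)
  ))
}

#' Validate a raw configuration document
#'
#' Takes the parsed form of a configuration document (a list with top-level
#' keys `assessment`, `sites`, `services`, and optionally `factors` and
#' `reference_points`) and returns a validated [cei_config()] object with
#' defaults filled in. Errors name the offending identifier.
#'
#' @param raw A list, typically from [yaml::read_yaml()] or
#'   [jsonlite::fromJSON()]. A machine-readable description of the schema
#'   ships as `system.file("extdata", "config-schema.json",
#'   package = "ceindex")`.
#' @return A `cei_config` object.
#' @export
validate_config <- function(raw) {
  if (!is.list(raw)) {
    abort("configuration must parse to a list", class = "cei_config_error")
  }
  for (key in c("assessment", "sites", "services")) {
    if (is.null(raw[[key]])) {
      abort(sprintf("configuration is missing the top-level key '%s'", key),
            class = "cei_config_error")
    }
  }
  a <- raw$assessment
  cei_config(
    evaluation_year = a$evaluation_year %||%
      abort("assessment$evaluation_year is required", class = "cei_config_error"),
    sites = raw$sites,
    services = raw$services,
    factors = raw$factors,
    window_years = a$window_years %||% 5L,
    beta = a$beta %||% 0.67,
    outlier_k = a$outlier_k %||% 2,
    report_scale = a$report_scale %||% "percent100",
    min_trend_points = a$min_trend_points %||% 3L,
    pr_years = a$pr_years %||% "evaluation",
    reference_points = raw$reference_points
  )
}

#' Read / write a configuration document
#'
#' Configuration files are YAML (`.yaml`/`.yml`) or JSON (`.json`) with
#' top-level keys `assessment`, `sites`, `services`, `factors`,
#' `reference_points`. `write_cei_config()` serializes a validated
#' configuration back to YAML; re-reading the file reproduces the same
#' configuration object.
#'
#' @param path File path.
#' @return `read_cei_config()` returns a `cei_config`;
#'   `write_cei_config()` returns `path` invisibly.
#' @export
read_cei_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("configuration file not found: %s", path),
          class = "cei_config_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(raw)
}

#' @rdname read_cei_config
#' @param config A `cei_config` object.
#' @export
write_cei_config <- function(config, path) {
  stopifnot(inherits(config, "cei_config"))
  yaml::write_yaml(as_config_list(config), path)
  invisible(path)
}

#' Convert a configuration back to its document form
#'
#' @param config A `cei_config` object.
#' @return A plain list mirroring the on-disk schema, suitable for
#'   serialization to YAML or JSON.
#' @export
as_config_list <- function(config) {
  stopifnot(inherits(config, "cei_config"))
  drop_na <- function(row) {
    row <- as.list(row)
    row[!vapply(row, function(v) length(v) == 1 && is.na(v), logical(1))]
  }
  tbl_rows <- function(tbl) {
    if (nrow(tbl) == 0) return(list())
    unname(lapply(seq_len(nrow(tbl)), function(i) drop_na(tbl[i, ])))
  }
  out <- list(
    assessment = list(
      evaluation_year = config$evaluation_year,
      window_years = config$window_years,
      beta = config$beta,
      outlier_k = config$outlier_k,
      report_scale = config$report_scale,
      min_trend_points = config$min_trend_points,
      pr_years = config$pr_years
    ),
    sites = tbl_rows(config$sites),
    services = tbl_rows(config$services),
    factors = tbl_rows(config$factors)
  )
  if (!is.null(config$reference_points)) {
    out$reference_points <- config$reference_points
  }
  out
}

#' @export
print.cei_config <- function(x, ...) {
  cat(sprintf("<cei_config> evaluation year %d, window %d years\n",
              x$evaluation_year, x$window_years))
  cat(sprintf("  beta = %g, outlier_k = %g, scale = %s\n",
              x$beta, x$outlier_k, x$report_scale))
  cat(sprintf("  %d sites, %d services, %d factors\n",
              nrow(x$sites), nrow(x$services), nrow(x$factors)))
  invisible(x)
}

# ---- internal normalizers ---------------------------------------------------

.check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name),
          class = "cei_config_error")
  }
}

.rows_to_tibble <- function(x, what) {
  if (is.null(x)) return(tibble())
  if (is.data.frame(x)) return(as_tibble(x))
  if (is.list(x)) {
    rows <- lapply(x, function(row) as_tibble(row[!vapply(row, is.null, logical(1))]))
    return(dplyr::bind_rows(rows))
  }
  abort(sprintf("`%s` must be a data frame or a list of records", what),
        class = "cei_config_error")
}

.require_column <- function(tbl, col, what) {
  if (!col %in% names(tbl) || any(is.na(tbl[[col]])) || any(tbl[[col]] == "")) {
    abort(sprintf("every %s record needs a non-empty '%s'", what, col),
          class = "cei_config_error")
  }
}

.fill_column <- function(tbl, col, default) {
  if (!col %in% names(tbl)) tbl[[col]] <- default
  tbl
}

.check_enum <- function(values, allowed, what) {
  bad <- setdiff(unique(values[!is.na(values)]), allowed)
  if (length(bad) > 0) {
    abort(sprintf("invalid %s '%s' (allowed: %s)", what, bad[1],
                  paste(allowed, collapse = ", ")),
          class = "cei_config_error")
  }
}

.as_sites <- function(sites) {
  tbl <- .rows_to_tibble(sites, "sites")
  if (nrow(tbl) == 0) {
    abort("at least one site must be declared", class = "cei_config_error")
  }
  .require_column(tbl, "site_id", "site")
  tbl$site_id <- as.character(tbl$site_id)
  tbl <- .fill_column(tbl, "name", NA_character_)
  tbl <- .fill_column(tbl, "natural_or_artificial", NA_character_)
  tbl <- .fill_column(tbl, "area_m2", NA_real_)
  tbl <- .fill_column(tbl, "coastline_m", NA_real_)
  tbl$name <- as.character(tbl$name)
  tbl$natural_or_artificial <- as.character(tbl$natural_or_artificial)
  tbl$area_m2 <- as.numeric(tbl$area_m2)
  tbl$coastline_m <- as.numeric(tbl$coastline_m)
  .check_enum(tbl$natural_or_artificial, .site_types, "natural_or_artificial")
  dup <- tbl$site_id[duplicated(tbl$site_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate site_id '%s'", dup[1]), class = "cei_config_error")
  }
  if (any(!is.na(tbl$area_m2) & tbl$area_m2 <= 0) ||
      any(!is.na(tbl$coastline_m) & tbl$coastline_m <= 0)) {
    abort("site area_m2 and coastline_m must be positive when given",
          class = "cei_config_error")
  }
  tbl[, c("site_id", "name", "natural_or_artificial", "area_m2", "coastline_m")]
}

.as_services <- function(services) {
  tbl <- .rows_to_tibble(services, "services")
  if (nrow(tbl) == 0) {
    abort("at least one service must be declared", class = "cei_config_error")
  }
  .require_column(tbl, "service_id", "service")
  tbl$service_id <- as.character(tbl$service_id)
  tbl <- .fill_column(tbl, "name", NA_character_)
  tbl <- .fill_column(tbl, "index_description", NA_character_)
  tbl <- .fill_column(tbl, "spatial_basis", "per_unit_area")
  tbl <- .fill_column(tbl, "temporal_statistic", "annual_mean")
  tbl <- .fill_column(tbl, "unit", NA_character_)
  for (col in c("name", "index_description", "spatial_basis",
                "temporal_statistic", "unit")) {
    tbl[[col]] <- as.character(tbl[[col]])
  }
  tbl$spatial_basis[is.na(tbl$spatial_basis)] <- "per_unit_area"
  tbl$temporal_statistic[is.na(tbl$temporal_statistic)] <- "annual_mean"
  .check_enum(tbl$spatial_basis, .spatial_bases, "spatial_basis")
  .check_enum(tbl$temporal_statistic, .temporal_statistics, "temporal_statistic")
  dup <- tbl$service_id[duplicated(tbl$service_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate service_id '%s'", dup[1]),
          class = "cei_config_error")
  }
  tbl[, c("service_id", "name", "index_description", "spatial_basis",
          "temporal_statistic", "unit")]
}

.empty_factors <- function() {
  tibble(
    factor_id = character(), service_id = character(), kind = character(),
    lo_threshold = numeric(), hi_threshold = numeric(), direction = character(),
    qualitative_magnitude = numeric(), weight = numeric(),
    description = character()
  )
}

.as_factors <- function(factors) {
  if (is.null(factors)) return(.empty_factors())
  tbl <- .rows_to_tibble(factors, "factors")
  if (nrow(tbl) == 0) return(.empty_factors())
  .require_column(tbl, "factor_id", "factor")
  .require_column(tbl, "service_id", "factor")
  .require_column(tbl, "kind", "factor")
  tbl$factor_id <- as.character(tbl$factor_id)
  tbl$service_id <- as.character(tbl$service_id)
  tbl$kind <- as.character(tbl$kind)
  tbl <- .fill_column(tbl, "lo_threshold", NA_real_)
  tbl <- .fill_column(tbl, "hi_threshold", NA_real_)
  tbl <- .fill_column(tbl, "direction", "increasing_good")
  tbl <- .fill_column(tbl, "qualitative_magnitude", 0.5)
  tbl <- .fill_column(tbl, "weight", 1)
  tbl <- .fill_column(tbl, "description", NA_character_)
  tbl$lo_threshold <- as.numeric(tbl$lo_threshold)
  tbl$hi_threshold <- as.numeric(tbl$hi_threshold)
  tbl$direction <- as.character(tbl$direction)
  tbl$direction[is.na(tbl$direction)] <- "increasing_good"
  tbl$qualitative_magnitude <- as.numeric(tbl$qualitative_magnitude)
  tbl$qualitative_magnitude[is.na(tbl$qualitative_magnitude)] <- 0.5
  tbl$weight <- as.numeric(tbl$weight)
  tbl$weight[is.na(tbl$weight)] <- 1
  tbl$description <- as.character(tbl$description)
  .check_enum(tbl$kind, .factor_kinds, "factor kind")
  .check_enum(tbl$direction, .factor_directions, "factor direction")

  for (i in seq_len(nrow(tbl))) {
    fid <- tbl$factor_id[i]
    if (tbl$kind[i] == "quantitative") {
      if (is.na(tbl$lo_threshold[i]) || is.na(tbl$hi_threshold[i])) {
        abort(sprintf("quantitative factor '%s' needs lo_threshold and hi_threshold",
                      fid),
              class = "cei_config_error")
      }
      if (tbl$lo_threshold[i] >= tbl$hi_threshold[i]) {
        abort(sprintf("factor '%s': lo_threshold must be below hi_threshold", fid),
              class = "cei_config_error")
      }
    } else {
      if (!is.na(tbl$lo_threshold[i]) || !is.na(tbl$hi_threshold[i])) {
        abort(sprintf("qualitative factor '%s' must not carry thresholds", fid),
              class = "cei_config_error")
      }
      if (tbl$qualitative_magnitude[i] <= 0 || tbl$qualitative_magnitude[i] > 1) {
        abort(sprintf("factor '%s': qualitative_magnitude must lie in (0, 1]", fid),
              class = "cei_config_error")
      }
    }
    if (tbl$weight[i] <= 0) {
      abort(sprintf("factor '%s': weight must be positive", fid),
            class = "cei_config_error")
    }
  }
  key <- paste(tbl$factor_id, tbl$service_id)
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate factor declaration '%s'", dup[1]),
          class = "cei_config_error")
  }
  tbl[, names(.empty_factors())]
}

.window_years <- function(config) {
  seq(config$evaluation_year - config$window_years + 1L, config$evaluation_year)
}
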