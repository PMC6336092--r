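#' Read indicator time series
#'
#' Reads a tidy delimited file with one record per (site, service, year):
#' columns `site_id`, `service_id`, `year`, `value`. `value` is the raw
#' indicator for the service in its own unit (e.g. g/m2 of commercially
#' important species, visitors per m2 per year), non-negative, computed
#' under the spatial/temporal convention declared for the service.
#'
#' @param path CSV file path (UTF-8, one header row).
#' @return A tibble with columns `site_id`, `service_id`, `year` (integer),
#'   `value` (double).
#' @export
read_indicator_series <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .check_columns(tbl, c("site_id", "service_id", "year", "value"), path)
  tibble(
    site_id = as.character(tbl$site_id),
    service_id = as.character(tbl$service_id),
    year = as.integer(tbl$year),
    value = as.numeric(tbl$value)
  )
}

#' Read environmental factor observations
#'
#' Reads one record per (site, service, factor, year): columns `site_id`,
#' `service_id`, `factor_id`, `year`, and exactly one of `value` (a
#' measured quantity, for quantitative factors) or `state` (`"positive"`,
#' `"negative"`, or `"unknown"`, for qualitative factors).
#'
#' @param path CSV file path.
#' @return A tibble with columns `site_id`, `service_id`, `factor_id`,
#'   `year`, `value`, `state`.
#' @export
read_factor_observations <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .check_columns(tbl, c("site_id", "service_id", "factor_id", "year"), path)
  tbl <- .fill_column(tbl, "value", NA_real_)
  tbl <- .fill_column(tbl, "state", NA_character_)
  tibble(
    site_id = as.character(tbl$site_id),
    service_id = as.character(tbl$service_id),
    factor_id = as.character(tbl$factor_id),
    year = as.integer(tbl$year),
    value = as.numeric(tbl$value),
    state = as.character(tbl$state)
  )
}

.check_columns <- function(tbl, cols, path) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "cei_data_error")
  }
}

# Cross-checks data tables against a validated configuration; errors name
# the first offending identifier.
.check_indicator_data <- function(ind, config) {
  stopifnot(is.data.frame(ind))
  .check_columns(ind, c("site_id", "service_id", "year", "value"), "indicators")
  unknown_site <- setdiff(unique(ind$site_id), config$sites$site_id)
  if (length(unknown_site) > 0) {
    abort(sprintf("indicator data refers to undeclared site '%s'",
                  unknown_site[1]),
          class = "cei_data_error")
  }
  unknown_svc <- setdiff(unique(ind$service_id), config$services$service_id)
  if (length(unknown_svc) > 0) {
    abort(sprintf("indicator data refers to undeclared service '%s'",
                  unknown_svc[1]),
          class = "cei_data_error")
  }
  if (any(!is.na(ind$value) & ind$value < 0)) {
    abort("indicator values must be non-negative", class = "cei_data_error")
  }
  key <- paste(ind$site_id, ind$service_id, ind$year)
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate indicator record for (%s)", dup[1]),
          class = "cei_data_error")
  }
  invisible(ind)
}

.check_factor_data <- function(fobs, config) {
  if (is.null(fobs)) return(invisible(NULL))
  .check_columns(fobs, c("site_id", "service_id", "factor_id", "year"),
                 "factor observations")
  fobs <- .fill_column(fobs, "value", NA_real_)
  fobs <- .fill_column(fobs, "state", NA_character_)
  unknown_site <- setdiff(unique(fobs$site_id), config$sites$site_id)
  if (length(unknown_site) > 0) {
    abort(sprintf("factor data refers to undeclared site '%s'",
                  unknown_site[1]),
          class = "cei_data_error")
  }
  key_def <- paste(config$factors$factor_id, config$factors$service_id)
  key_obs <- paste(fobs$factor_id, fobs$service_id)
  unknown <- setdiff(unique(key_obs), key_def)
  if (length(unknown) > 0) {
    abort(sprintf("factor data refers to undeclared factor/service pair '%s'",
                  unknown[1]),
          class = "cei_data_error")
  }
  .check_enum(fobs$state, .factor_states, "factor state")
  kind <- config$factors$kind[match(key_obs, key_def)]
  bad_q <- which(kind == "quantitative" & is.na(fobs$value))
  if (length(bad_q) > 0) {
    abort(sprintf("quantitative factor '%s' observation at %s/%d has no value",
                  fobs$factor_id[bad_q[1]], fobs$site_id[bad_q[1]],
                  fobs$year[bad_q[1]]),
          class = "cei_data_error")
  }
  bad_s <- which(kind == "qualitative" & is.na(fobs$state))
  if (length(bad_s) > 0) {
    abort(sprintf("qualitative factor '%s' observation at %s/%d has no state",
                  fobs$factor_id[bad_s[1]], fobs$site_id[bad_s[1]],
                  fobs$year[bad_s[1]]),
          class = "cei_data_error")
  }
  both <- which(!is.na(fobs$value) & !is.na(fobs$state))
  if (length(both) > 0) {
    abort("factor observations must populate exactly one of value/state",
          class = "cei_data_error")
  }
  invisible(fobs)
}
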