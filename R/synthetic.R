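#' Declare a synthetic assessment scenario
#'
#' A scenario fully determines a multi-site assessment input panel with
#' known ground truth: per (site, service) a base indicator level, a true
#' linear trend, Gaussian observation noise, and an outlier injection
#' rate; plus deterministic trajectories or state schedules for the
#' environmental factors. The same seed always reproduces the same panel
#' byte for byte.
#'
#' @param sites,services,factors As in [cei_config()].
#' @param baselines A data frame with one row per (site, service):
#'   `site_id`, `service_id`, `X0` (indicator level in the first window
#'   year, >= 0), `slope` (true change per year), `noise_sd` (Gaussian
#'   observation noise sd, >= 0), `outlier_rate` (probability that a
#'   yearly value receives a multiplicative shock, in `[0, 1)`).
#' @param factor_schedule Optional data frame with one row per (site,
#'   service, factor): `site_id`, `service_id`, `factor_id`, and either
#'   `value0`/`value_slope` (quantitative trajectory, linear in time,
#'   noise-free) or `state` (constant qualitative state).
#' @param evaluation_year,window_years,beta As in [cei_config()].
#' @param seed Integer RNG seed.
#' @param outlier_multiplier Range of the uniform multiplicative shock
#'   applied to injected outliers (default 4 to 8, comfortably outside a
#'   2-sigma band for moderate noise).
#' @return A `cei_scenario` object for [generate_panel()].
#' @export
scenario_spec <- function(sites, services, baselines,
                          factors = NULL, factor_schedule = NULL,
                          evaluation_year = 2013L, window_years = 5L,
                          beta = 0.67, seed = 1L,
                          outlier_multiplier = c(4, 8)) {
  baselines <- as_tibble(baselines)
  .check_columns(baselines, c("site_id", "service_id", "X0", "slope",
                              "noise_sd", "outlier_rate"), "baselines")
  if (any(baselines$X0 < 0) || any(baselines$noise_sd < 0) ||
      any(baselines$outlier_rate < 0 | baselines$outlier_rate >= 1)) {
    abort("baselines need X0 >= 0, noise_sd >= 0, outlier_rate in [0, 1)",
          class = "cei_scenario_error")
  }
  if (!is.null(factor_schedule)) {
    factor_schedule <- as_tibble(factor_schedule)
    .check_columns(factor_schedule, c("site_id", "service_id", "factor_id"),
                   "factor_schedule")
    factor_schedule <- .fill_column(factor_schedule, "value0", NA_real_)
    factor_schedule <- .fill_column(factor_schedule, "value_slope", 0)
    factor_schedule <- .fill_column(factor_schedule, "state", NA_character_)
    factor_schedule$value_slope[is.na(factor_schedule$value_slope)] <- 0
  }
  stopifnot(length(outlier_multiplier) == 2, all(outlier_multiplier > 1))
  config <- cei_config(
    evaluation_year = evaluation_year, sites = sites, services = services,
    factors = factors, window_years = window_years, beta = beta
  )
  structure(
    list(config = config,
         baselines = dplyr::arrange(baselines, .data$site_id, .data$service_id),
         factor_schedule = factor_schedule,
         seed = as.integer(seed),
         outlier_multiplier = as.numeric(outlier_multiplier)),
    class = "cei_scenario"
  )
}

#' Simulate one indicator time series
#'
#' Draws yearly values `X(t) = max(0, X0 + slope * (t - t0) + eps)` with
#' `eps ~ N(0, noise_sd^2)` (truncation at zero keeps indicator values in
#' their physical range; it slightly biases series whose mean is within a
#' few sd of zero). With probability `outlier_rate` a yearly value is
#' multiplied by a uniform shock, emulating the occasional aberrant survey
#' value that the screening stage is meant to catch. Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param X0 Level in the first year.
#' @param slope True change per year.
#' @param noise_sd Observation noise standard deviation.
#' @param years Calendar years to simulate.
#' @param outlier_rate Per-year shock probability.
#' @param outlier_multiplier Shock range (uniform).
#' @return A tibble with `year`, `value`, `is_outlier`.
#' @export
simulate_indicator_series <- function(X0, slope, noise_sd, years,
                                      outlier_rate = 0,
                                      outlier_multiplier = c(4, 8)) {
  years <- as.integer(years)
  mu <- X0 + slope * (years - years[1])
  value <- pmax(0, mu + rnorm(length(years), 0, noise_sd))
  shock <- runif(length(years)) < outlier_rate
  if (any(shock)) {
    value[shock] <- value[shock] *
      runif(sum(shock), outlier_multiplier[1], outlier_multiplier[2])
  }
  tibble(year = years, value = value, is_outlier = shock)
}

#' Generate a complete synthetic assessment panel
#'
#' Realizes a [scenario_spec()]: indicator series for every (site,
#' service) baseline, factor observations for every scheduled factor and
#' window year, the matching configuration, and a ground-truth record
#' carrying, per (site, service), the true slope, the noise-free
#' evaluation-year status and reference point, the true trend, PR and
#' sustainability scores implied by the noise-free inputs, and whether the
#' noise-free projection would hit the reference ceiling. Ground truth is
#' computed directly from the scenario arithmetic, not by running the
#' scoring pipeline.
#'
#' @param spec A `cei_scenario`.
#' @return A `cei_panel` list: `indicators`, `factor_obs`, `config`,
#'   `ground_truth` (tibble), `spec`.
#' @export
#' @examples
#' panel <- generate_panel(tokyo_bay_scenario(seed = 1))
#' head(panel$indicators)
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "cei_scenario"))
  set.seed(spec$seed)
  cfg <- spec$config
  yrs <- .window_years(cfg)
  first <- yrs[1]

  ind <- dplyr::bind_rows(lapply(seq_len(nrow(spec$baselines)), function(i) {
    b <- spec$baselines[i, ]
    sim <- simulate_indicator_series(b$X0, b$slope, b$noise_sd, yrs,
                                     b$outlier_rate, spec$outlier_multiplier)
    tibble(site_id = b$site_id, service_id = b$service_id,
           year = sim$year, value = sim$value, is_outlier = sim$is_outlier)
  }))

  fobs <- NULL
  if (!is.null(spec$factor_schedule)) {
    sched <- spec$factor_schedule
    fobs <- dplyr::bind_rows(lapply(seq_len(nrow(sched)), function(i) {
      s <- sched[i, ]
      if (!is.na(s$value0)) {
        tibble(site_id = s$site_id, service_id = s$service_id,
               factor_id = s$factor_id, year = yrs,
               value = s$value0 + s$value_slope * (yrs - first),
               state = NA_character_)
      } else {
        tibble(site_id = s$site_id, service_id = s$service_id,
               factor_id = s$factor_id, year = yrs,
               value = NA_real_, state = s$state)
      }
    }))
  }

  truth <- .panel_ground_truth(spec, yrs)

  structure(
    list(indicators = ind[, c("site_id", "service_id", "year", "value")],
         outlier_mask = ind[, c("site_id", "service_id", "year", "is_outlier")],
         factor_obs = fobs, config = cfg, ground_truth = truth, spec = spec),
    class = "cei_panel"
  )
}

# Deterministic (noise-free) ground truth, computed from the scenario
# arithmetic alone: mu(site, service, year) = X0 + slope * (year - first),
# X_R from the maximum mu, trend from the true slope, PR from the
# scheduled evaluation-year factor states/values.
.panel_ground_truth <- function(spec, yrs) {
  cfg <- spec$config
  first <- yrs[1]
  b <- spec$baselines
  mu_eval <- b$X0 + b$slope * (cfg$evaluation_year - first)
  mu_max <- pmax(b$X0, b$X0 + b$slope * (max(yrs) - first)) # linear => max at an end
  X_R <- tapply(mu_max, b$service_id, max)

  rows <- lapply(seq_len(nrow(b)), function(i) {
    sid <- b$service_id[i]
    st <- b$site_id[i]
    xr <- unname(X_R[[sid]])
    x_true <- if (xr > 0) mu_eval[i] / xr else NA_real_
    T_true <- if (xr > 0) max(-1, min(1, 5 * b$slope[i] / xr)) else NA_real_

    pr_scores <- numeric()
    if (!is.null(spec$factor_schedule)) {
      sched <- spec$factor_schedule[
        spec$factor_schedule$site_id == st &
          spec$factor_schedule$service_id == sid, , drop = FALSE]
      defs <- cfg$factors
      pr_scores <- vapply(seq_len(nrow(sched)), function(j) {
        s <- sched[j, ]
        f <- defs[defs$factor_id == s$factor_id & defs$service_id == sid, ]
        if (nrow(f) != 1) return(NA_real_)
        if (f$kind == "quantitative") {
          v <- s$value0 + s$value_slope * (cfg$evaluation_year - first)
          # piecewise-linear model, written out directly
          raw <- -1 + 2 * (v - f$lo_threshold) / (f$hi_threshold - f$lo_threshold)
          sc <- max(-1, min(1, raw))
          if (f$direction == "decreasing_good") -sc else sc
        } else {
          switch(s$state, positive = f$qualitative_magnitude,
                 negative = -f$qualitative_magnitude, NA_real_)
        }
      }, numeric(1))
    }
    pr_scores <- pr_scores[!is.na(pr_scores)]
    PR_true <- if (length(pr_scores) > 0) mean(pr_scores) else NA_real_
    pr_used <- if (is.na(PR_true)) 0 else PR_true
    mult <- 1 + cfg$beta * T_true + (1 - cfg$beta) * pr_used
    xF_raw <- mult * x_true
    tibble(
      site_id = st, service_id = sid,
      true_slope = b$slope[i], noise_sd = b$noise_sd[i],
      X_R_true = xr, x_true = x_true, T_true = T_true,
      PR_true = PR_true, pr_evaluated = !is.na(PR_true),
      S_true = mult - 1,
      xF_true_raw = xF_raw, clamped_true = !is.na(xF_raw) && xF_raw > 1
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a synthetic panel to disk
#'
#' Emits exactly the file set the ingestion layer reads -- `config.yaml`,
#' `indicators.csv`, and `factor_observations.csv` -- plus
#' `ground_truth.json`. Output is deterministic: re-generating a panel
#' from the same seed and writing it again produces byte-identical files.
#'
#' @param panel A `cei_panel` from [generate_panel()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named paths written.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "cei_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    config = file.path(dir, "config.yaml"),
    indicators = file.path(dir, "indicators.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_cei_config(panel$config, paths$config)
  readr::write_csv(panel$indicators, paths$indicators, progress = FALSE)
  if (!is.null(panel$factor_obs)) {
    paths$factor_obs <- file.path(dir, "factor_observations.csv")
    readr::write_csv(panel$factor_obs, paths$factor_obs, progress = FALSE)
  }
  jsonlite::write_json(panel$ground_truth, paths$ground_truth,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' A four-tidal-flat demonstration scenario
#'
#' The packaged default scenario emulates a Tokyo-Bay-like assessment: two
#' artificial and two natural tidal flats compared over a five-year window
#' ending in 2013, across six services with mixed per-unit-area and
#' whole-site indicators. The food-provision conceptual model combines a
#' quantitative dissolved-oxygen factor (thresholds 2 and 6 mg/L), a
#' quantitative chlorophyll-a factor, and qualitative factors (blue tide,
#' predators, ground stability, juvenile supply, management, species
#' protection); the research service deliberately has no factors, so its
#' projection reflects the trend alone. Baseline levels, trends and noise
#' (roughly 10% of level, occasional 5% outlier shocks) are set to
#' plausible magnitudes for an enclosed-bay monitoring program.
#'
#' @param seed Integer RNG seed for [generate_panel()].
#' @return A `cei_scenario`.
#' @export
#' @examples
#' spec <- tokyo_bay_scenario(seed = 7)
#' panel <- generate_panel(spec)
tokyo_bay_scenario <- function(seed = 42L) {
  sites <- tibble(
    site_id = c("SN", "UK", "TR", "OR"),
    name = c("Shiosai Nagisa", "Umi Koen", "Tama River flat", "Obitsu River flat"),
    natural_or_artificial = c("artificial", "artificial", "natural", "natural"),
    area_m2 = c(438, 150000, 250000, 6500000),
    coastline_m = c(35, 800, 2500, 3500)
  )
  services <- tibble(
    service_id = c("food", "coastal_protection", "recreation", "research",
                   "suspended_removal", "diversity"),
    name = c("Food provision", "Coastal protection", "Recreation",
             "Research", "Suspended material removal", "Degree of diversity"),
    index_description = c(
      "Wet weight of commercially important species",
      "Wave energy reduction ratio",
      "Visitors for the purpose of recreation",
      "Papers and reports",
      "Bivalve water filtration volume",
      "Shannon-Wiener diversity index"),
    spatial_basis = c("per_unit_area", "whole_site", "per_unit_area",
                      "whole_site", "per_unit_area", "whole_site"),
    temporal_statistic = c("annual_mean", "annual_mean", "annual_total",
                           "annual_total", "annual_mean", "annual_mean"),
    unit = c("g/m2", "-", "people/m2/year", "papers/year", "g/m2/day", "-")
  )
  factors <- dplyr::bind_rows(
    factor_definition("anoxic_water", "food", kind = "quantitative",
                      lo_threshold = 2, hi_threshold = 6,
                      description = "DO concentration, mg/L"),
    factor_definition("primary_productivity", "food", kind = "quantitative",
                      lo_threshold = 1, hi_threshold = 5,
                      description = "Chl-a concentration, ug/L"),
    factor_definition("blue_tide", "food", kind = "qualitative"),
    factor_definition("predatory_species", "food", kind = "qualitative"),
    factor_definition("stability_of_ground", "food", kind = "qualitative"),
    factor_definition("source_of_juveniles", "food", kind = "qualitative"),
    factor_definition("management_of_ground", "food", kind = "qualitative"),
    factor_definition("protection_of_species", "food", kind = "qualitative"),
    factor_definition("management_of_ground", "coastal_protection",
                      kind = "qualitative"),
    factor_definition("seawall_inspection", "coastal_protection",
                      kind = "qualitative"),
    factor_definition("accessibility", "recreation", kind = "qualitative"),
    factor_definition("attracting_visitors", "recreation", kind = "qualitative"),
    factor_definition("healthy_habitat", "recreation", kind = "qualitative"),
    factor_definition("anoxic_water", "suspended_removal", kind = "quantitative",
                      lo_threshold = 2, hi_threshold = 6),
    factor_definition("blue_tide", "suspended_removal", kind = "qualitative"),
    factor_definition("stability_of_ground", "suspended_removal",
                      kind = "qualitative"),
    factor_definition("alien_species", "diversity", kind = "qualitative"),
    factor_definition("protection_of_species", "diversity", kind = "qualitative"),
    factor_definition("stability_of_ground", "diversity", kind = "qualitative")
  )

  base <- function(service_id, X0, slope) {
    tibble(site_id = c("SN", "UK", "TR", "OR"), service_id = service_id,
           X0 = X0, slope = slope, noise_sd = 0.1 * X0,
           outlier_rate = 0.05)
  }
  baselines <- dplyr::bind_rows(
    base("food", c(30, 12, 10, 13), c(-2, 0.3, 0.1, 0.4)),
    base("coastal_protection", c(0.55, 0.70, 0.60, 0.68), c(0, 0.005, -0.005, 0.002)),
    base("recreation", c(0.0, 2.4, 0.02, 0.015), c(0, -0.02, 0, 0.001)),
    base("research", c(4, 1, 6, 5), c(0.5, 0, 0.6, 0.7)),
    base("suspended_removal", c(45, 10, 7, 4), c(1.5, 0.3, 0.1, 0.1)),
    base("diversity", c(2.0, 2.4, 2.1, 1.9), c(0.04, 0.10, -0.01, 0.01))
  )

  qual <- function(service_id, factor_id, states) {
    tibble(site_id = c("SN", "UK", "TR", "OR"), service_id = service_id,
           factor_id = factor_id, state = states)
  }
  quant <- function(service_id, factor_id, value0, value_slope = 0) {
    tibble(site_id = c("SN", "UK", "TR", "OR"), service_id = service_id,
           factor_id = factor_id, value0 = value0, value_slope = value_slope)
  }
  schedule <- dplyr::bind_rows(
    quant("food", "anoxic_water", c(3.2, 5.5, 4.8, 3.9)),
    quant("food", "primary_productivity", c(4.5, 3.5, 4.0, 5.2)),
    qual("food", "blue_tide", c("negative", "positive", "positive", "negative")),
    qual("food", "predatory_species", c("negative", "positive", "negative", "positive")),
    qual("food", "stability_of_ground", c("negative", "positive", "positive", "positive")),
    qual("food", "source_of_juveniles", c("positive", "positive", "positive", "positive")),
    qual("food", "management_of_ground", c("positive", "positive", "negative", "negative")),
    qual("food", "protection_of_species", c("negative", "positive", "unknown", "positive")),
    qual("coastal_protection", "management_of_ground",
         c("positive", "positive", "negative", "positive")),
    qual("coastal_protection", "seawall_inspection",
         c("positive", "positive", "negative", "positive")),
    qual("recreation", "accessibility", c("negative", "positive", "negative", "negative")),
    qual("recreation", "attracting_visitors", c("negative", "positive", "negative", "negative")),
    qual("recreation", "healthy_habitat", c("negative", "negative", "positive", "positive")),
    quant("suspended_removal", "anoxic_water", c(3.2, 5.5, 4.8, 3.9)),
    qual("suspended_removal", "blue_tide",
         c("negative", "positive", "positive", "negative")),
    qual("suspended_removal", "stability_of_ground",
         c("negative", "positive", "positive", "positive")),
    qual("diversity", "alien_species", c("negative", "negative", "negative", "positive")),
    qual("diversity", "protection_of_species", c("negative", "positive", "positive", "positive")),
    qual("diversity", "stability_of_ground", c("negative", "positive", "positive", "positive"))
  )

  scenario_spec(
    sites = sites, services = services, baselines = baselines,
    factors = factors, factor_schedule = schedule,
    evaluation_year = 2013L, window_years = 5L, beta = 0.67, seed = seed
  )
}
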