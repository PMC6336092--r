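# Shared fixtures and independent oracles for the test suite.

# Literal, loop-free restatement of the screening-then-max rule, kept
# deliberately independent of screen_outliers()/reference_point():
# exclude values beyond k sample standard deviations from the pooled mean
# (single pass), then take the maximum of what remains.
brute_force_screened_max <- function(values, k = 2) {
  if (length(values) < 2) return(max(values))
  m <- mean(values)
  s <- sd(values)
  keep <- if (is.na(s) || s == 0) rep(TRUE, length(values)) else {
    abs(values - m) <= k * s
  }
  max(values[keep])
}

# Minimal one-service configuration used by pipeline-level unit tests.
small_config <- function(beta = 0.67, sites = c("A", "B"), ...) {
  cei_config(
    evaluation_year = 2013,
    sites = data.frame(site_id = sites),
    services = data.frame(service_id = c("food", "research")),
    factors = rbind(
      factor_definition("anoxic_water", "food", kind = "quantitative",
                        lo_threshold = 2, hi_threshold = 6),
      factor_definition("blue_tide", "food", kind = "qualitative")
    ),
    beta = beta,
    ...
  )
}

# Tidy indicator rows for one (site, service) across the 2009-2013 window.
ind_rows <- function(site_id, service_id, values, years = 2009:2013) {
  data.frame(site_id = site_id, service_id = service_id,
             year = years[seq_along(values)], value = values)
}

# A deterministic two-site, two-service scenario: no observation noise, no
# outlier injection, chosen so that no site hits the projection ceiling.
noiseless_scenario <- function(seed = 1L) {
  sites <- data.frame(site_id = c("A", "B"),
                      natural_or_artificial = c("artificial", "natural"))
  services <- data.frame(service_id = c("food", "research"))
  factors <- rbind(
    factor_definition("anoxic_water", "food", kind = "quantitative",
                      lo_threshold = 2, hi_threshold = 6),
    factor_definition("blue_tide", "food", kind = "qualitative"),
    factor_definition("stability_of_ground", "food", kind = "qualitative")
  )
  baselines <- data.frame(
    site_id = rep(c("A", "B"), each = 2),
    service_id = rep(c("food", "research"), 2),
    X0 = c(30, 4, 20, 6),
    slope = c(-1.5, -0.2, 0.5, -0.3),
    noise_sd = 0,
    outlier_rate = 0
  )
  schedule <- data.frame(
    site_id = c("A", "A", "A", "B", "B", "B"),
    service_id = "food",
    factor_id = rep(c("anoxic_water", "blue_tide", "stability_of_ground"), 2),
    value0 = c(3.0, NA, NA, 5.0, NA, NA),
    value_slope = 0,
    state = c(NA, "negative", "negative", NA, "positive", "positive")
  )
  scenario_spec(sites, services, baselines, factors = factors,
                factor_schedule = schedule, seed = seed)
}
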