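test_that("noiseless series let the trend fit recover the slope exactly", {
  spec <- noiseless_scenario()
  panel <- generate_panel(spec)
  for (i in seq_len(nrow(spec$baselines))) {
    b <- spec$baselines[i, ]
    series <- panel$indicators[panel$indicators$site_id == b$site_id &
                                 panel$indicators$service_id == b$service_id, ]
    tr <- fit_trend(series$year, series$value)
    expect_equal(tr$slope, b$slope, tolerance = 1e-10)
    expect_equal(tr$se, 0, tolerance = 1e-8)
  }
})

test_that("noiseless end-to-end scores match the analytic ground truth", {
  panel <- generate_panel(noiseless_scenario())
  a <- score_assessment(panel$config, panel$indicators, panel$factor_obs)
  merged <- merge(a$scores, panel$ground_truth,
                  by = c("site_id", "service_id"))
  expect_equal(nrow(merged), nrow(a$scores))
  for (i in seq_len(nrow(merged))) {
    row <- merged[i, ]
    expect_equal(row$x, row$x_true, tolerance = 1e-9)
    expect_equal(row$T, row$T_true, tolerance = 1e-9)
    if (row$pr_evaluated) {
      expect_equal(row$PR, row$PR_true, tolerance = 1e-12)
    } else {
      expect_true(is.na(row$PR))
      expect_true(grepl("PR_DEFAULTED", row$flags))
    }
    if (row$x > 0 && !row$clamped_true) {
      expect_equal(row$S, row$S_true, tolerance = 1e-9)
    }
  }
})

test_that("a fixed seed reproduces the panel exactly", {
  p1 <- generate_panel(tokyo_bay_scenario(seed = 3))
  p2 <- generate_panel(tokyo_bay_scenario(seed = 3))
  expect_identical(p1$indicators, p2$indicators)
  expect_identical(p1$factor_obs, p2$factor_obs)
  p3 <- generate_panel(tokyo_bay_scenario(seed = 4))
  expect_false(identical(p1$indicators, p3$indicators))
})

test_that("the demonstration scenario runs end to end with the right shape", {
  panel <- generate_panel(tokyo_bay_scenario(seed = 5))
  expect_equal(sort(unique(panel$indicators$site_id)),
               c("OR", "SN", "TR", "UK"))
  expect_equal(length(unique(panel$indicators$year)), 5L)
  a <- score_assessment(panel$config, panel$indicators, panel$factor_obs)
  m <- format_score_matrix(a)
  expect_equal(names(m), c("service_id", "SN", "UK", "TR", "OR"))
  expect_equal(nrow(m), 6L)
  # research has no conceptual model: its projection must reflect trend only
  research <- a$scores[a$scores$service_id == "research", ]
  expect_true(all(is.na(research$PR)))
  expect_true(all(grepl("PR_DEFAULTED", research$flags)))
})

test_that("outlier injection produces values the screening stage catches", {
  set.seed(2)
  sim <- simulate_indicator_series(10, 0, 0.5, 2000:2099, outlier_rate = 0.2)
  expect_gt(sum(sim$is_outlier), 0)
  expect_gt(min(sim$value[sim$is_outlier]), max(sim$value[!sim$is_outlier]))
})

test_that("written panels include ground truth and reload cleanly", {
  dir <- withr::local_tempdir()
  panel <- generate_panel(noiseless_scenario())
  paths <- write_panel(panel, dir)
  expect_true(all(file.exists(unlist(paths))))
  truth <- jsonlite::fromJSON(paths$ground_truth)
  expect_setequal(
    c("site_id", "service_id", "true_slope", "X_R_true", "T_true", "S_true"),
    intersect(names(truth),
              c("site_id", "service_id", "true_slope", "X_R_true", "T_true",
                "S_true"))
  )
  cfg <- read_cei_config(paths$config)
  expect_equal(cfg, panel$config)
  ind <- read_indicator_series(paths$indicators)
  expect_equal(ind, panel$indicators)
})

test_that("invalid scenario baselines are rejected", {
  sites <- data.frame(site_id = "A")
  services <- data.frame(service_id = "food")
  bad <- data.frame(site_id = "A", service_id = "food", X0 = 1, slope = 0,
                    noise_sd = -1, outlier_rate = 0)
  expect_error(scenario_spec(sites, services, bad),
               class = "cei_scenario_error")
})
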