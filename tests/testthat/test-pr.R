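do_model <- factor_definition("anoxic_water", "food", kind = "quantitative",
                              lo_threshold = 2, hi_threshold = 6)

test_that("the dissolved-oxygen model hits its printed anchors", {
  expect_equal(quantitative_factor_score(2.0, do_model), -1.0)
  expect_equal(quantitative_factor_score(6.0, do_model), +1.0)
  expect_equal(quantitative_factor_score(4.0, do_model), 0.0)
  expect_equal(quantitative_factor_score(3.0, do_model), -0.5)
  # saturation beyond the thresholds
  expect_equal(quantitative_factor_score(0.5, do_model), -1.0)
  expect_equal(quantitative_factor_score(9.0, do_model), +1.0)
  expect_true(is.na(quantitative_factor_score(NA, do_model)))
})

test_that("qualitative factors score plus/minus their magnitude", {
  bt <- factor_definition("blue_tide", "food", kind = "qualitative")
  expect_equal(qualitative_factor_score("positive", bt), +0.5)
  expect_equal(qualitative_factor_score("negative", bt), -0.5)
  expect_true(is.na(qualitative_factor_score("unknown", bt)))

  strong <- factor_definition("x", "food", kind = "qualitative",
                              qualitative_magnitude = 0.8)
  expect_equal(qualitative_factor_score(c("positive", "negative"), strong),
               c(0.8, -0.8))
  expect_error(qualitative_factor_score("maybe", bt),
               class = "cei_config_error")
})

test_that("kind mismatches are rejected", {
  bt <- factor_definition("blue_tide", "food", kind = "qualitative")
  expect_error(quantitative_factor_score(3, bt), class = "cei_pr_error")
  expect_error(qualitative_factor_score("positive", do_model),
               class = "cei_pr_error")
})

test_that("quantitative scores are monotone, continuous and bounded", {
  v <- seq(-5, 15, by = 0.01)
  s <- quantitative_factor_score(v, do_model)
  expect_true(all(diff(s) >= 0))
  expect_true(all(abs(diff(s)) < 0.01)) # no jumps at the grid scale
  expect_true(all(s >= -1 & s <= 1))
})

test_that("decreasing_good mirrors the increasing_good model", {
  dec <- factor_definition("salinity_excess", "food", kind = "quantitative",
                           lo_threshold = 2, hi_threshold = 6,
                           direction = "decreasing_good")
  v <- seq(0, 10, by = 0.25)
  expect_equal(quantitative_factor_score(v, dec),
               -quantitative_factor_score(v, do_model))
  expect_equal(quantitative_factor_score(2, dec), +1)
  expect_equal(quantitative_factor_score(6, dec), -1)
})

test_that("PR aggregation is the mean of scored factors", {
  expect_equal(aggregate_pr(c(0.5, -0.5)), 0)
  expect_equal(aggregate_pr(c(-1.0, -0.5, 0.5, -0.5, 0.5)), -0.2)
  expect_true(is.na(aggregate_pr(c(NA, NA))))
  expect_true(is.na(aggregate_pr(numeric(0))))
  expect_equal(aggregate_pr(c(0.5, NA, -1)), -0.25) # NA excluded, not zeroed
})

test_that("weighted aggregation matches a direct weighted mean", {
  set.seed(61)
  for (rep in 1:50) {
    n <- sample(1:8, 1)
    s <- runif(n, -1, 1)
    s[runif(n) < 0.2] <- NA
    w <- runif(n, 0.5, 3)
    got <- aggregate_pr(s, w)
    ok <- !is.na(s)
    if (!any(ok)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, sum(s[ok] * w[ok]) / sum(w[ok]))
      expect_gte(got, min(s[ok]))
      expect_lte(got, max(s[ok]))
    }
  }
})

test_that("diagnostics list negative factors worst-first", {
  scores <- data.frame(
    factor_id = c("anoxic_water", "blue_tide", "source_of_juveniles"),
    score = c(-1, -0.5, 0.5)
  )
  expect_equal(factor_diagnostics(scores), c("anoxic_water", "blue_tide"))
  expect_equal(factor_diagnostics(data.frame(factor_id = "a", score = 0.2)),
               character(0))
  tie <- data.frame(factor_id = c("zeta", "alpha"), score = c(-0.5, -0.5))
  expect_equal(factor_diagnostics(tie), c("alpha", "zeta"))
})
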