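test_that("exact linear data recovers the slope with a degenerate interval", {
  tr <- fit_trend(2009:2013, c(0.10, 0.12, 0.14, 0.16, 0.18))
  expect_equal(tr$slope, 0.02, tolerance = 1e-10)
  expect_equal(tr$T, 0.10, tolerance = 1e-10)
  expect_equal(tr$se, 0, tolerance = 1e-8)
  expect_equal(tr$T_lower, 0.10, tolerance = 1e-7)
  expect_equal(tr$T_upper, 0.10, tolerance = 1e-7)
  expect_equal(tr$n_points, 5L)
})

test_that("missing history yields a zero trend with flag", {
  tr <- fit_trend(integer(0), numeric(0))
  expect_equal(tr$T, 0)
  expect_equal(tr$T_lower, 0)
  expect_equal(tr$T_upper, 0)
  expect_true("NO_TREND_DATA" %in% tr$flags)

  # below the minimum point count the rule also applies
  tr2 <- fit_trend(2012:2013, c(0.5, 0.9))
  expect_equal(tr2$T, 0)
  expect_true("NO_TREND_DATA" %in% tr2$flags)
})

test_that("a flat series has zero trend and zero error", {
  tr <- fit_trend(2009:2013, rep(0.4, 5))
  expect_equal(tr$T, 0, tolerance = 1e-12)
  expect_equal(tr$se, 0, tolerance = 1e-8)
})

test_that("confidence half-width is 15 times the slope standard error", {
  expect_equal(trend_ci_halfwidth(0), 0)
  expect_equal(trend_ci_halfwidth(0.01), 0.15)
  expect_equal(trend_ci_halfwidth(0.1), 1.5)
  expect_error(trend_ci_halfwidth(-1), class = "cei_trend_error")
})

test_that("steep slopes clamp the score and wide errors clamp the bounds", {
  tr <- fit_trend(2009:2013, c(0.0, 0.25, 0.5, 0.75, 1.0))
  expect_equal(tr$T, 1) # 5 * 0.25 would be 1.25
  expect_true(tr$clamped)
  expect_true("CLAMPED_TREND" %in% tr$flags)

  set.seed(7)
  tr2 <- fit_trend(2009:2013, runif(5))
  expect_true(tr2$T_lower >= -1 && tr2$T_upper <= 1)
  expect_true(tr2$T_lower <= tr2$T && tr2$T <= tr2$T_upper)
})

test_that("identical years are rejected", {
  expect_error(fit_trend(rep(2013, 4), c(1, 2, 3, 4)),
               class = "cei_trend_error")
})

test_that("the trend is invariant to adding a constant to all statuses", {
  set.seed(31)
  for (rep in 1:25) {
    x <- runif(5)
    a <- fit_trend(2009:2013, x)
    b <- fit_trend(2009:2013, x + 0.37)
    expect_equal(a$T, b$T, tolerance = 1e-10)
    expect_equal(a$se, b$se, tolerance = 1e-10)
  }
})

test_that("NA statuses are dropped before fitting", {
  tr <- fit_trend(2009:2013, c(0.1, NA, 0.14, 0.16, 0.18))
  expect_equal(tr$n_points, 4L)
  expect_equal(tr$slope, 0.02, tolerance = 1e-10)
})
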