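test_that("future status reduces to present status under neutral conditions", {
  x <- c(0, 0.3, 0.8, 1)
  expect_equal(future_status(x, T = 0, PR = 0), x)
})

test_that("future status clamps at the reference ceiling and floors at zero", {
  # multiplier 1 + 0.67 + 0.33 = 2 puts 0.5 exactly at the ceiling
  expect_equal(future_status(0.5, T = 1, PR = 1, beta = 0.67), 1.0)
  expect_equal(future_status(0.6, T = 1, PR = 1, beta = 0.67, clamp = FALSE),
               1.2)
  expect_equal(future_status(0.6, T = 1, PR = 1, beta = 0.67), 1.0)
  # multiplier 0 regardless of beta
  for (b in c(0, 0.33, 0.67, 1)) {
    expect_equal(future_status(0.5, T = -1, PR = -1, beta = b), 0)
  }
  expect_true(is.na(future_status(NA, 0.5, 0.5)))
})

test_that("service score is the mean of present and future status", {
  expect_equal(service_score(1, 1), 100)
  expect_equal(service_score(0, 0), 0)
  expect_equal(service_score(0.6, 0.4), 50)
  expect_equal(service_score(0.6, 0.4, report_scale = "unit"), 0.5)
  expect_true(is.na(service_score(NA, 0.4)))
})

test_that("sustainability is the relative status change, undefined at zero", {
  expect_equal(sustainability(0.5, 0.5), 0)
  expect_equal(sustainability(0.5, 0.6), 0.2)
  expect_true(is.na(sustainability(0, 0)))
  expect_true(is.na(sustainability(0, 0.1)))
})

test_that("composed stages agree with the closed form", {
  # x = 0.8, T = 0.1, PR = 0.2, beta = 0.67:
  # S = 0.67*0.1 + 0.33*0.2 = 0.133; I = 0.8*(2 + 0.133)/2*100 = 85.32
  beta <- 0.67
  x <- 0.8
  x_F <- future_status(x, T = 0.1, PR = 0.2, beta = beta)
  expect_equal(sustainability(x, x_F), 0.133, tolerance = 1e-12)
  expect_equal(service_score(x, x_F), 85.32, tolerance = 1e-12)
})

test_that("sustainability equals the weighted trend/PR sum absent clamping", {
  set.seed(88)
  n <- 2000
  x <- runif(n, 0.01, 1)
  T <- runif(n, -1, 1)
  PR <- runif(n, -1, 1)
  beta <- runif(n)
  raw <- future_status(x, T, PR, beta, clamp = FALSE)
  keep <- raw <= 1
  S <- sustainability(x[keep], raw[keep])
  expect_true(all(abs(S - (beta[keep] * T[keep] + (1 - beta[keep]) * PR[keep]))
                  <= 1e-9))
  expect_true(all(abs(S) <= 1 + 1e-12))
})

test_that("the service score is monotone in each input before clamping", {
  grid <- seq(-1, 1, by = 0.25)
  beta <- 0.67
  I_of <- function(x, T, PR) {
    service_score(x, future_status(x, T, PR, beta, clamp = FALSE),
                  report_scale = "unit")
  }
  xs <- seq(0, 1, by = 0.1)
  for (T in grid) for (PR in grid) {
    # multiplier (2 + beta*T + (1-beta)*PR)/2 >= 1/2 > 0, so I rises with x
    expect_true(all(diff(I_of(xs, T, PR)) >= -1e-12))
  }
  for (x in c(0.2, 0.7)) for (PR in grid) {
    expect_true(all(diff(I_of(x, grid, PR)) >= -1e-12))
  }
  for (x in c(0.2, 0.7)) for (T in grid) {
    expect_true(all(diff(I_of(x, T, grid)) >= -1e-12))
  }
})
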