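test_that("Shannon-Wiener index matches hand-computed values", {
  expect_equal(shannon_diversity(5), 0)
  expect_equal(shannon_diversity(c(10, 10)), log(2))
  # p = {0.25, 0.25, 0.5}: -sum(p ln p) = 1.0397
  expect_equal(shannon_diversity(c(10, 10, 20)), 1.0397, tolerance = 1e-4)
  expect_error(shannon_diversity(c(0, 0)), class = "cei_empty_community")
  expect_error(shannon_diversity(c(-1, 2)), class = "cei_indicator_error")
})

test_that("Shannon-Wiener index agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(404)
  for (rep in 1:25) {
    counts <- rpois(sample(2:30, 1), lambda = 8)
    if (sum(counts) == 0) counts <- counts + 1
    expect_equal(shannon_diversity(counts),
                 unname(vegan::diversity(counts, index = "shannon")),
                 tolerance = 1e-12)
  }
})

test_that("H' is maximal for uniform communities and invariant to scaling", {
  set.seed(11)
  for (rep in 1:20) {
    S <- sample(2:15, 1)
    counts <- runif(S, 1, 100)
    h <- shannon_diversity(counts)
    expect_lte(h, log(S) + 1e-12)
    expect_equal(shannon_diversity(rep(4, S)), log(S))
    expect_equal(shannon_diversity(counts * 7), h) # effort scaling
    expect_equal(shannon_diversity(sample(counts)), h) # relabeling
  }
})

test_that("weighted rare-species count is the weight/count dot product", {
  expect_equal(weighted_rare_species(c(A = 2, B = 3), c(A = 1, B = 1)), 5)
  expect_equal(weighted_rare_species(numeric(0), c(A = 1)), 0)
  expect_equal(weighted_rare_species(c(CR = 1, VU = 2),
                                     c(CR = 3, EN = 2, VU = 1)), 5)
  expect_error(weighted_rare_species(c(CR = 1, DD = 2), c(CR = 3)),
               regexp = "DD", class = "cei_indicator_error")
})
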