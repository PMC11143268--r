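test_that("dip statistic matches analytic values for atomic distributions", {
  # balanced two-point: the largest possible dip
  expect_equal(dip_statistic(c(rep(0, 15), rep(1, 15))), 0.25, tolerance = 1e-7)
  # unbalanced two-point masses (p, 1-p): D = min(p, 1-p)/2
  expect_equal(dip_statistic(c(rep(0, 10), rep(1, 40))), 0.1, tolerance = 1e-7)
  expect_equal(dip_statistic(c(rep(-3, 30), rep(5, 70))), 0.15, tolerance = 1e-7)
  # three equal atoms: D = 1/6; equally spaced distinct values: D = 1/(2n)
  expect_equal(dip_statistic(rep(c(0, 1, 2), 10)), 1/6, tolerance = 1e-7)
  expect_equal(dip_statistic(1:20), 1/40, tolerance = 1e-7)
  # two heavy far atoms dominate: masses (.4, .2, .4) -> D = 0.2
  expect_equal(dip_statistic(rep(c(0, 0, 1, 2, 2), 20)), 0.2, tolerance = 1e-7)
})

test_that("dip agrees with the independent brute-force unimodal fit", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                sample(0:3, n, replace = TRUE),  # heavy ties
                c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 6)))
    expect_equal(dip_statistic(x), dip_brute(x), tolerance = 1e-6,
                 info = paste(round(x, 3), collapse = ","))
  }
})

test_that("dip bounds, invariances and degenerate inputs", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:80, 1)
    x <- rnorm(n)
    d <- dip_statistic(x)
    expect_gte(d, 1 / (2 * n) - 1e-9)
    expect_lte(d, 0.25 + 1e-9)
  }
  x <- runif(100)
  expect_equal(dip_statistic(x), dip_statistic(5 - 3 * x), tolerance = 1e-7)
  expect_equal(dip_statistic(x), dip_statistic(c(x, x)), tolerance = 1e-7)
  expect_error(dip_statistic(c(1, 2, 3)), "at least 4")
  expect_equal(dip_statistic(rep(1, 10)), 0)
})

test_that("Monte-Carlo dip p-values separate bimodal from unimodal samples", {
  set.seed(1)
  bim <- c(rbeta(100, 1.5, 10), rbeta(100, 10, 1.5))
  p_bim <- dip_pvalue_mc(dip_statistic(bim), 200, n_null = 499, seed = 2)
  expect_lt(p_bim, 0.01)
  # calibration: unimodal Gaussians are mostly non-significant
  ps <- vapply(1:10, function(i) {
    x <- rnorm(200)
    dip_pvalue_mc(dip_statistic(x), 200, n_null = 199, seed = 100 + i)
  }, 0)
  expect_gte(mean(ps > 0.05), 0.8)
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("adapted dip and bimodality index follow their closed forms", {
  expect_equal(adapted_dip(0.05, 100), 0.5)
  expect_equal(adapted_dip(0, 1000), 0)
  expect_equal(adapted_dip(0.25, 30), sqrt(30) * 0.25, tolerance = 1e-6)
  # the classification cutoff: D' = 0.5 maps to |BI| = e^{-1.5} = 0.2231
  expect_equal(abs(bimodality_index(0.5, -0.4)), exp(-1.5), tolerance = 1e-12)
  expect_equal(round(abs(bimodality_index(0.5, 1)), 2), 0.22)
  expect_equal(bimodality_index(0.5, -0.4), +exp(-1.5))   # evergreen side
  expect_equal(bimodality_index(0, 0.4), -1)              # unimodal deciduous
  expect_equal(bimodality_index(0, 0), 0)                 # sign(0) = 0
  expect_lt(abs(bimodality_index(10, 1)), 1e-40)
})

test_that("BI magnitude is monotone in D-prime; sign comes from skewness only", {
  dp <- seq(0, 4, by = 0.05)
  bi <- abs(bimodality_index(dp, 1))
  expect_true(all(diff(bi) <= 0))
  expect_true(all(bimodality_index(dp, -2) >= 0))
  expect_true(all(bimodality_index(dp[-1], 3) < 0))
})

test_that("classify_bi applies the documented cutoffs and boundaries", {
  expect_equal(as.character(classify_bi(-0.5)), "deciduous_dominated")
  expect_equal(as.character(classify_bi(-0.22)), "bistable_deciduous")
  expect_equal(as.character(classify_bi(0)), "bistable_evergreen")
  expect_equal(as.character(classify_bi(0.22)), "bistable_evergreen")
  expect_equal(as.character(classify_bi(0.23)), "evergreen_dominated")
  expect_error(classify_bi(1.5), "<= 1")
})

test_that("skewness is bias-adjusted, sign-correct, and errors on degenerate input", {
  x <- c(0.2, 0.4, 0.6, 0.8)          # mirror pairs about 0.5
  expect_equal(sample_skewness(x), 0, tolerance = 1e-12)
  expect_lt(sample_skewness(c(0.9, 0.9, 0.9, 0.1)), 0)
  set.seed(3)
  expect_equal(sample_skewness(rexp(1e5)), 2, tolerance = 0.1)
  expect_error(sample_skewness(rep(0.5, 10)), "zero-variance")
})
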