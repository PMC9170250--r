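test_that("a noiseless cumulative Gaussian is recovered exactly", {
  x <- seq(-4, 4, by = 1)
  d <- data.frame(x = x, k = round(pnorm(x / 2) * 1e6), n = 1e6)
  f <- fit_cumulative_gaussian(d, lapse_mode = "none")
  expect_equal(f$mu, 0, tolerance = 1e-3)
  expect_equal(f$sigma, 2, tolerance = 1e-3)
  expect_gt(f$r_squared, 0.999)
})

test_that("the psychometric fit is shift-equivariant", {
  set.seed(41)
  x <- seq(-8, 8, by = 2)
  k <- rbinom(length(x), 40, pnorm((x - 1) / 2.5))
  d <- data.frame(x = x, k = k, n = 40)
  f0 <- fit_cumulative_gaussian(d, "none")
  d7 <- transform(d, x = x + 7)
  f7 <- fit_cumulative_gaussian(d7, "none")
  expect_equal(f7$mu - f0$mu, 7, tolerance = 1e-4)
  expect_equal(f7$sigma, f0$sigma, tolerance = 1e-4)
})

test_that("identical responses raise the degenerate-data flag", {
  d <- data.frame(x = -3:3, k = 10, n = 10)
  f <- fit_cumulative_gaussian(d)
  expect_true(f$degenerate)
  expect_true(is.na(f$mu))
  d0 <- data.frame(x = -3:3, k = 0, n = 10)
  expect_true(fit_cumulative_gaussian(d0)$degenerate)
})

test_that("bias and threshold are recovered across seeded replicates", {
  # fine-grained visual grid of the unisensory experiment, sigma = 1.1
  locs <- av_conventions()$exp1_vis_locations
  ok <- logical(200)
  for (s in 1:200) {
    set.seed(s)
    k <- rbinom(length(locs), 15, pnorm(locs / 1.1))
    f <- fit_cumulative_gaussian(data.frame(x = locs, k = k, n = 15),
                                 "none", n_starts = 5, seed = s)
    ok[s] <- abs(f$mu) < 0.5 && abs(f$sigma - 1.1) / 1.1 < 0.3
  }
  expect_gte(mean(ok), 0.85)
})

test_that("flat observers fail the R^2 screening and are counted exactly", {
  # response rate pinned at one half carries no stimulus information
  set.seed(42)
  locs <- seq(-9, 9, by = 3)
  flat <- data.frame(x = locs, k = rbinom(7, 30, 0.5), n = 30)
  f <- fit_cumulative_gaussian(flat, "rate_only")
  expect_lt(goodness_of_fit(f), 0.5)
  # a simulated cohort of 31 with 6 flat observers: exactly 6 flagged
  flagged <- 0L
  for (i in 1:31) {
    set.seed(100 + i)
    pr <- if (i <= 6) rep(0.5, 7) else pnorm(locs / 3)
    dd <- data.frame(x = locs, k = rbinom(7, 30, pr), n = 30)
    fi <- fit_cumulative_gaussian(dd, "rate_only")
    if (fi$degenerate || goodness_of_fit(fi) < 0.5) flagged <- flagged + 1L
  }
  expect_identical(flagged, 6L)
})

test_that("model-consistent data drives R^2 toward one at large n", {
  x <- seq(-9, 9, by = 3)
  d <- data.frame(x = x, k = round(pnorm(x / 3) * 1e5), n = 1e5)
  f <- fit_cumulative_gaussian(d, "none")
  expect_gt(goodness_of_fit(f), 0.9999)
})

test_that("noiseless Gaussian curves are recovered exactly", {
  d <- data.frame(delta = seq(-24, 24, by = 6))
  d$prop <- 0.75 * exp(-(d$delta - 0)^2 / (2 * 30^2))
  f <- fit_gaussian_curve(d)
  expect_equal(f$amplitude, 0.75, tolerance = 1e-6)
  expect_equal(f$mean, 0, tolerance = 1e-6)
  expect_equal(f$width, 30, tolerance = 1e-6)
  expect_false(f$flat)
})

test_that("Gaussian curve fitting recovers noisy generating parameters", {
  deltas <- c(-24, -12, -6, -3, 0, 3, 6, 12, 24)
  ok <- logical(200)
  for (s in 1:200) {
    set.seed(300 + s)
    pr <- 0.75 * exp(-deltas^2 / (2 * 30^2))
    d <- data.frame(delta = deltas, prop = rbinom(9, 21, pr) / 21)
    f <- fit_gaussian_curve(d, seed = s)
    ok[s] <- abs(f$amplitude - 0.75) < 0.2 && abs(f$mean) < 10 &&
      abs(f$width - 30) / 30 < 0.75
  }
  expect_gte(mean(ok), 0.9)
})

test_that("Gaussian curve fit is reflection-symmetric in disparity", {
  set.seed(43)
  deltas <- c(-24, -12, -6, -3, 0, 3, 6, 12, 24)
  pr <- 0.8 * exp(-(deltas - 4)^2 / (2 * 18^2))
  d <- data.frame(delta = deltas, prop = pr + rnorm(9, 0, 0.02))
  f <- fit_gaussian_curve(d)
  dr <- data.frame(delta = -d$delta, prop = d$prop)
  fr <- fit_gaussian_curve(dr)
  expect_equal(fr$mean, -f$mean, tolerance = 1e-4)
  expect_equal(fr$amplitude, f$amplitude, tolerance = 1e-6)
  expect_equal(fr$width, f$width, tolerance = 1e-4)
})

test_that("constant proportions raise the flat-report flag", {
  d <- data.frame(delta = c(-24, -12, 0, 12, 24), prop = rep(0.55, 5))
  f <- fit_gaussian_curve(d)
  expect_true(f$flat)
})

test_that("the additive-bias variant shifts a reference Gaussian", {
  d <- data.frame(delta = seq(-24, 24, by = 6))
  d$prop <- 0.7 * exp(-d$delta^2 / (2 * 25^2))
  ref <- fit_gaussian_curve(d)
  same <- fit_gaussian_plus_bias(d, ref)
  expect_equal(same$baseline, 0, tolerance = 1e-6)
  expect_equal(predict(same, d), predict(ref, d), tolerance = 1e-6)
  lower <- transform(d, prop = prop - 0.1)
  fb <- fit_gaussian_plus_bias(lower, ref)
  expect_equal(fb$baseline, -0.1, tolerance = 1e-6)
})

test_that("cubic regression is exact on constructed data and flags linearity", {
  deltas <- c(-24, -12, -6, -3, 0, 3, 6, 12, 24)
  d <- data.frame(delta = deltas, bias = 0.5 * deltas - 5e-4 * deltas^3)
  f <- fit_cubic_regression(d)
  expect_equal(unname(f$coefficients),
               c(0, 0.5, 0, -5e-4), tolerance = 1e-8)
  lin <- data.frame(delta = deltas, bias = 0.3 * deltas)
  fl <- fit_cubic_regression(lin)
  expect_lt(abs(fl$coefficients[["a2"]]), 1e-10)
  expect_lt(abs(fl$coefficients[["a3"]]), 1e-10)
  expect_lt(fl$partial_r2_cubic, 1e-6)
})

test_that("nested R^2 never decreases with polynomial order", {
  set.seed(44)
  for (i in 1:20) {
    d <- data.frame(delta = c(-24, -12, -6, -3, 0, 3, 6, 12, 24),
                    bias = rnorm(9, 0, 2))
    r2 <- fit_cubic_regression(d)$r_squared_by_order
    expect_true(all(diff(r2) >= -1e-12))
    pr2 <- fit_cubic_regression(d)$partial_r2_cubic
    expect_gte(pr2, 0)
    expect_lte(pr2, 1)
  }
})

test_that("saturating causal-inference bias needs the cubic term more than fusion bias", {
  # model-predicted auditory bias against disparity: a causal-inference
  # observer saturates, a forced-fusion observer grows linearly
  pci <- observer_params(p_common = 0.5, sigma_a = 3,
                         sigma_v = c(high = 1, medium = 3, low = 8),
                         lapse_rate = 0)
  pff <- observer_params(p_common = 1, sigma_a = 3,
                         sigma_v = c(high = 1, medium = 3, low = 8),
                         lapse_rate = 0)
  deltas <- c(-24, -12, -6, -3, 0, 3, 6, 12, 24)
  bias_of <- function(p) vapply(deltas, function(dl) {
    locs <- seq(-30, 30, by = 3)
    pr <- response_prob_implicit(locs, locs - dl, p, "high")
    f <- fit_cumulative_gaussian(
      data.frame(x = locs, k = round(pr * 1e5), n = 1e5), "none")
    f$mu
  }, numeric(1))
  bci <- bias_of(pci)
  bff <- bias_of(pff)
  fci <- fit_cubic_regression(data.frame(delta = deltas, bias = bci))
  fff <- fit_cubic_regression(data.frame(delta = deltas, bias = bff))
  expect_gt(fci$partial_r2_cubic, fff$partial_r2_cubic)
  # saturation: CI bias at 24 deg grows less than twice the bias at 12 deg
  expect_lt(abs(bci[deltas == -24]), 2 * abs(bci[deltas == -12]))
})
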