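# a small, fast implicit data set: one reliability of the implicit task
fast_implicit_data <- function(params, seed = 1) {
  d <- simulate_observer(make_schedule_exp2(seed), params, seed)
  d[d$reliability == "medium", ]
}

fast_cfg <- function(free = c("p_common", "p_choice_implicit",
                              "lapse_rate"), ...) {
  fit_config(n_starts = 1L, quad_order = 9L, maxit = 400L, reltol = 1e-7,
             free = free, ...)
}

test_that("the trial likelihood is additive over duplicated data", {
  p <- test_params()
  d <- fast_implicit_data(p, 1)
  expect_equal(negative_log_likelihood(p, rbind(d, d), quad_order = 9),
               2 * negative_log_likelihood(p, d, quad_order = 9),
               tolerance = 1e-9)
})

test_that("a saturated lapse model attains the Bernoulli entropy bound", {
  p <- test_params()
  d <- fast_implicit_data(p, 2)
  rate <- mean(d$response == 1L)
  sat <- observer_params(lapse_rate = 1, lapse_bias = rate)
  n <- nrow(d)
  entropy_bound <- -n * (rate * log(rate) + (1 - rate) * log(1 - rate))
  expect_equal(negative_log_likelihood(sat, d, quad_order = 9),
               entropy_bound, tolerance = 1e-6)
})

test_that("generating parameters beat a p_common-shifted rival in likelihood", {
  truth <- observer_params(p_common = 0.5, sigma_a = 3,
                           sigma_v = c(high = 1, medium = 3, low = 8),
                           lapse_rate = 0.03)
  rival <- observer_params(p_common = 0.2, sigma_a = 3,
                           sigma_v = c(high = 1, medium = 3, low = 8),
                           lapse_rate = 0.03)
  wins <- 0L
  for (s in 1:100) {
    d <- simulate_observer(make_schedule_exp2(s), truth, 500 + s)
    ctx <- avci:::build_nll_context(d, 9)
    wins <- wins + (avci:::nll_from_context(truth, ctx) <
                      avci:::nll_from_context(rival, ctx))
  }
  expect_gte(wins, 95L)
})

test_that("fitting recovers the machinery contracts: AIC, variants, aggregate", {
  truth <- test_params()
  d <- fast_implicit_data(truth, 3)
  cfg <- fast_cfg(start = test_params())
  fit <- fit_subject(d, "full_CI", cfg)
  expect_s3_class(fit, "fitted_model")
  expect_equal(fit$aic, 2 * fit$n_free_params + 2 * fit$nll)
  expect_equal(fit$n_free_params, 3L)

  fit_a <- fit_subject(d, "alt_A_forced_fusion", cfg)
  expect_equal(fit_a$params$p_common, 1)
  expect_equal(fit_a$n_free_params, 2L)
  fit_b <- fit_subject(d, "alt_B_no_fusion", cfg)
  expect_equal(fit_b$params$p_common, 0)
  fit_c <- fit_subject(d, "alt_C_no_lapse_bias",
                       fast_cfg(free = c("p_common", "lapse_rate",
                                         "lapse_bias")))
  expect_equal(fit_c$params$lapse_bias, 0.5)
  fit_d <- fit_subject(d, "alt_D_choice_only", fit_config(
    n_starts = 1L, quad_order = 9L, maxit = 300L, start = truth))
  expect_setequal(fit_d$free, c("lapse_rate", "lapse_bias",
                                "p_choice_implicit"))

  # aggregate of a single subject equals the subject fit
  cohort <- list(list(data = d, params = truth, subject_id = "s1",
                      group = "control"))
  class(cohort) <- "av_cohort"
  agg <- fit_aggregate(cohort, "full_CI", cfg)
  expect_equal(agg$nll, fit$nll, tolerance = 1e-8)
  expect_equal(avci:::fitted_free_params(agg),
               avci:::fitted_free_params(fit), tolerance = 1e-6)

  # model comparison table
  tab <- compare_models(list(fit, fit_a, fit_b))
  expect_equal(tab$delta_aic[1], 0)
  expect_true(all(diff(tab$aic) >= 0))
  tab2 <- compare_models(list(fit, fit))
  expect_true(all(tab2$delta_aic == 0))
  d_other <- fast_implicit_data(truth, 4)
  fit_other <- fit_subject(d_other, "full_CI", cfg)
  expect_error(compare_models(list(fit, fit_other)), "different data")

  # serialization carries the estimates
  js <- fitted_model_to_json(fit)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$nll, fit$nll, tolerance = 1e-9)
  expect_equal(parsed$estimates$p_common, fit$params$p_common,
               tolerance = 1e-9)
})

test_that("EVE hits its analytic limits and honors the noise floor", {
  set.seed(51)
  n <- rep(30L, 40)
  truep <- runif(40, 0.1, 0.9)
  k <- rbinom(40, n, truep)
  # saturated model: per-condition empirical proportions
  expect_equal(eve_from_proportions(k, n, k / n), 1)
  # grand-mean model: centered on zero in expectation
  eves <- vapply(1:200, function(s) {
    set.seed(s)
    kk <- rbinom(40, n, truep)
    eve_from_proportions(kk, n, rep(mean(kk / n), 40))
  }, numeric(1))
  expect_lt(abs(mean(eves)), 0.05)
  # uninformative data: variance at the noise floor is flagged undefined
  expect_warning(out <- eve_from_proportions(rbinom(40, 30, 0.5), n,
                                             rep(0.5, 40)), "undefined")
  expect_true(is.na(out))
})

test_that("the generating model explains nearly all explainable variance", {
  truth <- test_params()
  good <- 0L
  for (s in 1:10) {
    d <- simulate_observer(make_schedule_exp2(s), truth, 700 + s)
    good <- good + (explainable_variance_explained(truth, d,
                                                   quad_order = 9) >= 0.9)
  }
  expect_gte(good, 9L)
})

test_that("bootstrap intervals nest across levels and are seed-stable", {
  set.seed(52)
  locs <- av_conventions()$exp1_vis_locations
  trials <- data.frame(x = rep(locs, each = 20))
  trials$response <- ifelse(runif(nrow(trials)) <
                              pnorm((trials$x - 0.8) / 2), 1L, -1L)
  trials$subject_id <- "s1"
  fit_fn <- function(d) {
    counts <- response_proportions(d, by = "x")
    f <- fit_cumulative_gaussian(
      data.frame(x = counts$x, k = counts$k, n = counts$n), "none",
      n_starts = 2)
    c(mu = f$mu, sigma = f$sigma)
  }
  ci <- bootstrap_ci(trials, fit_fn, level = c(0.68, 0.95), n_boot = 120,
                     seed = 9)
  ints <- ci$intervals
  for (pm in c("mu", "sigma")) {
    lo68 <- ints[ints$parameter == pm & ints$level == 0.68, ]
    lo95 <- ints[ints$parameter == pm & ints$level == 0.95, ]
    expect_gte(lo68$lower, lo95$lower)
    expect_lte(lo68$upper, lo95$upper)
  }
  ci2 <- bootstrap_ci(trials, fit_fn, level = c(0.68, 0.95), n_boot = 120,
                      seed = 9)
  expect_identical(ci$intervals, ci2$intervals)
})

test_that("bootstrap coverage of a location parameter is near nominal", {
  # 100 simulated data sets, 68% intervals for the psychometric bias
  locs <- av_conventions()$exp1_vis_locations
  fit_mu <- function(d) {
    counts <- response_proportions(d, by = "x")
    c(mu = fit_cumulative_gaussian(
      data.frame(x = counts$x, k = counts$k, n = counts$n), "none",
      n_starts = 1)$mu)
  }
  covered <- 0L
  for (s in 1:100) {
    set.seed(900 + s)
    trials <- data.frame(x = rep(locs, each = 12), subject_id = "s1")
    trials$response <- ifelse(runif(nrow(trials)) < pnorm(trials$x / 2),
                              1L, -1L)
    ci <- bootstrap_ci(trials, fit_mu, level = 0.68, n_boot = 100, seed = s)
    lo <- ci$intervals$lower[1]
    hi <- ci$intervals$upper[1]
    covered <- covered + (lo <= 0 && 0 <= hi)
  }
  expect_gte(covered, 55L)
  expect_lte(covered, 80L)
})

test_that("boundary regimes pull the fitted common prior to its edges", {
  # data generated by always-fuse / never-fuse observers drive the fitted
  # p_common to the matching boundary when the nuisance parameters are known
  cfg <- fast_cfg(free = c("p_common", "lapse_rate"),
                  start = observer_params(lapse_rate = 0.03))
  fuse <- observer_params(p_common = 1, lapse_rate = 0.03)
  d1 <- simulate_observer(make_schedule_exp2(7), fuse, 71)
  expect_gt(fit_subject(d1, "full_CI", cfg)$params$p_common, 0.9)
  split <- observer_params(p_common = 0, lapse_rate = 0.03)
  d0 <- simulate_observer(make_schedule_exp2(8), split, 81)
  expect_lt(fit_subject(d0, "full_CI", cfg)$params$p_common, 0.1)
})

test_that("the recovery report is deterministic and well-formed", {
  truth <- test_params()
  sched <- make_schedule_exp2(1)
  sched <- sched[sched$reliability == "medium", ]
  cfg <- fast_cfg(start = test_params())
  rep1 <- parameter_recovery_report(truth, list(sched), n_reps = 2,
                                    seed = 3, config = cfg)
  rep2 <- parameter_recovery_report(truth, list(sched), n_reps = 2,
                                    seed = 3, config = cfg)
  expect_identical(rep1, rep2)
  expect_setequal(rep1$parameter,
                  c("p_common", "p_choice_implicit", "lapse_rate"))
  expect_equal(rep1$bias, rep1$mean_est - rep1$true, tolerance = 1e-12)
})
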