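test_that("closed-form likelihoods match dense numerical integration", {
  set.seed(11)
  worst <- 0
  for (i in 1:50) {
    p <- random_params()
    rel <- rel_sample()
    xa <- runif(1, -25, 25)
    xv <- runif(1, -25, 25)
    for (common in c(TRUE, FALSE)) {
      ora <- oracle_likelihood(xa, xv, p, rel, common)
      val <- if (common) likelihood_common(xa, xv, p, rel)
             else likelihood_separate(xa, xv, p, rel)
      worst <- max(worst, abs(val - ora) / ora)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("common-source likelihood is symmetric under modality swap", {
  set.seed(12)
  for (i in 1:10) {
    p <- random_params()
    xa <- runif(1, -20, 20)
    xv <- runif(1, -20, 20)
    swapped <- observer_params(
      sigma_a = p$sigma_v[["medium"]],
      sigma_v = c(high = 1, medium = p$sigma_a, low = 2),
      mu_a_prior = p$mu_v_prior, sigma_a_prior = p$sigma_v_prior,
      mu_v_prior = p$mu_a_prior, sigma_v_prior = p$sigma_a_prior)
    expect_equal(likelihood_common(xa, xv, p, "medium"),
                 likelihood_common(xv, xa, swapped, "medium"),
                 tolerance = 1e-12)
  }
})

test_that("separate-source likelihood factorizes and is translation-equivariant", {
  p <- test_params()
  l <- likelihood_separate(3, -5, p, "medium")
  fa <- dnorm(3, p$mu_a_prior, sqrt(p$sigma_a^2 + p$sigma_a_prior^2))
  fv <- dnorm(-5, p$mu_v_prior,
              sqrt(p$sigma_v[["medium"]]^2 + p$sigma_v_prior^2))
  expect_equal(l, fa * fv, tolerance = 1e-12)
  shifted <- observer_params(sigma_a = p$sigma_a, sigma_v = p$sigma_v,
                             mu_a_prior = p$mu_a_prior + 7,
                             sigma_a_prior = p$sigma_a_prior,
                             mu_v_prior = p$mu_v_prior + 7,
                             sigma_v_prior = p$sigma_v_prior)
  expect_equal(likelihood_separate(3 + 7, -5 + 7, shifted, "medium"), l,
               tolerance = 1e-12)
})

test_that("coincident measurements under tight noise favor a common source", {
  p <- observer_params(sigma_a = 1, sigma_v = c(high = 1, medium = 1,
                                                low = 1),
                       sigma_a_prior = 30, sigma_v_prior = 30)
  expect_gt(likelihood_common(0, 0, p, "high"),
            likelihood_separate(0, 0, p, "high"))
})

test_that("cause posterior obeys its limits, normalization and disparity decay", {
  p <- test_params()
  expect_equal(posterior_common(4, -7, observer_params(p_common = 1),
                                "medium"), 1)
  expect_equal(posterior_common(4, -7, observer_params(p_common = 0),
                                "medium"), 0)
  # posterior over the two structures always sums to one (complement check)
  l1 <- likelihood_common(3, -2, p, "low")
  l2 <- likelihood_separate(3, -2, p, "low")
  w1 <- posterior_common(3, -2, p, "low")
  expect_equal(w1 + (1 - p$p_common) * l2 /
                 (p$p_common * l1 + (1 - p$p_common) * l2), 1,
               tolerance = 1e-12)
  # non-increasing in |Xa - Xv| at a fixed midpoint, symmetric setup
  ps <- observer_params(p_common = 0.5, sigma_a = 2,
                        sigma_v = c(high = 2, medium = 3, low = 8))
  gaps <- seq(0, 40, by = 2)
  post <- posterior_common(gaps / 2, -gaps / 2, ps, "high")
  expect_true(all(diff(post) <= 1e-12))
})

test_that("implicit decision matches the dense-grid posterior oracle", {
  set.seed(13)
  worst <- 0
  for (i in 1:50) {
    p <- random_params()
    rel <- rel_sample()
    xa <- runif(1, -15, 15)
    xv <- runif(1, -15, 15)
    closed <- implicit_prob_right(xa, xv, p, rel)
    ora <- oracle_p_right(xa, xv, p, rel)
    worst <- max(worst, abs(closed - ora))
    expect_identical(implicit_decision(xa, xv, p, rel),
                     ifelse(closed >= 0.5, 1L, -1L))
  }
  expect_lt(worst, 1e-4)
})

test_that("implicit decision follows unambiguous evidence and degenerate priors", {
  p <- observer_params(p_common = 0.5, p_choice_implicit = 0.5)
  expect_identical(implicit_decision(4, 4, p, "high"), 1L)
  expect_identical(implicit_decision(-4, -4, p, "high"), -1L)
  # degenerate choice prior dominates any measurement
  p1 <- observer_params(p_choice_implicit = 1)
  expect_identical(implicit_decision(-10, -10, p1, "high"), 1L)
  p0 <- observer_params(p_choice_implicit = 0)
  expect_identical(implicit_decision(10, 10, p0, "high"), -1L)
})

test_that("explicit decision thresholds the cause posterior at the matched criterion", {
  set.seed(14)
  for (i in 1:100) {
    p <- random_params()
    rel <- rel_sample()
    xa <- runif(1, -25, 25)
    xv <- runif(1, -25, 25)
    t <- criterion_from_p_combined(p$p_combined, p$p_common)
    via_criterion <- posterior_common(xa, xv, p, rel) >= t
    expect_identical(explicit_decision(xa, xv, p, rel),
                     ifelse(via_criterion, 1L, 2L))
  }
  # degenerate mixtures
  expect_identical(explicit_decision(0, 20, observer_params(p_combined = 1),
                                     "high"), 1L)
  expect_identical(explicit_decision(0, 0, observer_params(p_combined = 0),
                                     "high"), 2L)
})

test_that("explicit mixture weight reproduces the full prior-over-categories rule", {
  set.seed(15)
  for (i in 1:200) {
    pc <- runif(1)
    pch <- runif(1)
    alpha <- runif(1)
    l1 <- rexp(1)
    l2 <- rexp(1)
    # direct evaluation of the category-posterior comparison
    lhs <- pch * (l1 * (pc + alpha * (1 - pc)) +
                    l2 * (1 - pc - alpha * (1 - pc)))
    rhs <- (1 - pch) * (l1 * pc * (1 - alpha) +
                          l2 * (1 - pc * (1 - alpha)))
    q <- p_combined_from_components(pc, pch, alpha)
    expect_gte(q, 0)
    expect_lte(q, 1)
    expect_identical(lhs > rhs, l1 * q > l2 * (1 - q))
  }
  # complete task learning: the report category equals the cause variable,
  # so the choice prior (not p_common) governs the mixture
  expect_equal(p_combined_from_components(0.3, 0.7, 1), 0.7)
  expect_equal(p_combined_from_components(0.9, 0.5, 1), 0.5)
})

test_that("criterion form of the explicit weight behaves as derived", {
  expect_equal(p_combined_from_criterion(0.5, 0.3), 0.3)  # unbiased criterion
  expect_equal(p_combined_from_criterion(0.25, 0.5), 0.75)
  ts <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(p_combined_from_criterion(ts, 0.4)) < 0))
  # inverse round-trip
  expect_equal(criterion_from_p_combined(
    p_combined_from_criterion(0.37, 0.62), 0.62), 0.37, tolerance = 1e-12)
  expect_error(p_combined_from_criterion(0, 0.5), "strictly inside")
})
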