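# shared observer parameter sets for tests

# generic asymmetric observer: exercises non-zero prior means so that
# symmetry cannot mask indexing errors
test_params <- function(...) {
  observer_params(sigma_a = 2, sigma_v = c(high = 1, medium = 3, low = 8),
                  mu_a_prior = 1, sigma_a_prior = 12,
                  mu_v_prior = -2, sigma_v_prior = 18,
                  p_common = 0.5, p_choice_implicit = 0.55,
                  p_combined = 0.55, lapse_rate = 0.02, lapse_bias = 0.4,
                  ...)
}

# draw a random-but-valid parameter set (used by oracle property tests)
random_params <- function() {
  observer_params(
    sigma_a = runif(1, 1, 6),
    sigma_v = c(high = runif(1, 0.5, 2), medium = runif(1, 2, 6),
                low = runif(1, 6, 15)),
    mu_a_prior = runif(1, -4, 4), sigma_a_prior = runif(1, 8, 40),
    mu_v_prior = runif(1, -4, 4), sigma_v_prior = runif(1, 8, 40),
    p_common = runif(1, 0.05, 0.95),
    p_choice_implicit = runif(1, 0.2, 0.8),
    p_combined = runif(1, 0.05, 0.95),
    lapse_rate = runif(1, 0, 0.2), lapse_bias = runif(1, 0.2, 0.8))
}

rel_sample <- function() sample(c("high", "medium", "low"), 1)
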