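#' Causal-inference observer: likelihoods and cause posterior
#'
#' The observer measures noisy cue locations `x_a ~ N(eps_a, sigma_a^2)` and
#' `x_v ~ N(eps_v, sigma_v^2)` and entertains two causal structures: one
#' common source (`C = 1`), in which case both measurements arise from a
#' single location drawn from the fused natural prior, or two independent
#' sources (`C = 2`). Both marginal likelihoods have closed forms (products
#' and convolutions of Gaussians); they are computed in log space and
#' combined with the prior `p_common` into the cause posterior.
#'
#' `likelihood_common()` is the single-source marginal: the integral over the
#' shared location of the two sensory likelihoods times the normalized fused
#' natural prior (normalizer `N(mu_a; mu_v, sigma_a_prior^2 +
#' sigma_v_prior^2)`). `likelihood_separate()` factorizes into two
#' independent 1-D convolutions, one per modality.
#'
#' All functions are vectorized over `x_a`, `x_v`.
#'
#' @param x_a,x_v Measured auditory and visual locations, degrees.
#' @param params An [observer_params()] object.
#' @param reliability Visual reliability level: `"high"`, `"medium"` or
#'   `"low"`.
#' @param log If `TRUE` return log densities / log probabilities.
#' @return Density values (or their logs) for the likelihoods; a probability
#'   in \[0, 1\] for [posterior_common()].
#' @examples
#' p <- observer_params(p_common = 0.5)
#' posterior_common(0, 0, p, "high") > posterior_common(0, 20, p, "high")
#' @export
likelihood_common <- function(x_a, x_v, params, reliability, log = FALSE) {
  ll <- log_lik_common(x_a, x_v, params$sigma_a^2,
                       params$sigma_v[[reliability]]^2, params)
  if (log) ll else exp(ll)
}

#' @rdname likelihood_common
#' @export
likelihood_separate <- function(x_a, x_v, params, reliability, log = FALSE) {
  ll <- log_lik_separate(x_a, x_v, params$sigma_a^2,
                         params$sigma_v[[reliability]]^2, params)
  if (log) ll else exp(ll)
}

#' @rdname likelihood_common
#' @export
posterior_common <- function(x_a, x_v, params, reliability) {
  s2a <- params$sigma_a^2
  s2v <- params$sigma_v[[reliability]]^2
  post_common_from_logliks(log_lik_common(x_a, x_v, s2a, s2v, params),
                           log_lik_separate(x_a, x_v, s2a, s2v, params),
                           params$p_common)
}

log_lik_common <- function(x_a, x_v, s2a, s2v, params) {
  s2ap <- params$sigma_a_prior^2
  s2vp <- params$sigma_v_prior^2
  v1 <- 1 / (1 / s2a + 1 / s2v)            # sensory fusion
  m1 <- v1 * (x_a / s2a + x_v / s2v)
  vp <- 1 / (1 / s2ap + 1 / s2vp)          # fused natural prior
  mp <- vp * (params$mu_a_prior / s2ap + params$mu_v_prior / s2vp)
  stats::dnorm(x_a, x_v, sqrt(s2a + s2v), log = TRUE) +
    stats::dnorm(m1, mp, sqrt(v1 + vp), log = TRUE)
}

log_lik_separate <- function(x_a, x_v, s2a, s2v, params) {
  stats::dnorm(x_a, params$mu_a_prior,
               sqrt(s2a + params$sigma_a_prior^2), log = TRUE) +
    stats::dnorm(x_v, params$mu_v_prior,
                 sqrt(s2v + params$sigma_v_prior^2), log = TRUE)
}

post_common_from_logliks <- function(l1, l2, p_common) {
  if (p_common >= 1) return(rep(1, length(l1)))
  if (p_common <= 0) return(rep(0, length(l1)))
  a <- log(p_common) + l1
  b <- log1p(-p_common) + l2
  exp(a - logaddexp(a, b))
}

#' Implicit (localization) decision rule
#'
#' In the implicit task the observer reports whether the auditory source lay
#' left or right of straight ahead. The trial-category posterior
#' `p(D = +1 | x_a, x_v)` mixes, over the cause variable with weights from
#' [posterior_common()], the posterior mass of the (auditory) source location
#' on the positive half-line under each causal structure; within each branch
#' the task prior restricts the source to one half-line (Heaviside prior,
#' with the matching truncated-prior normalizer) and the Bernoulli choice
#' prior `p_choice_implicit` weighs the two categories. All half-line masses
#' are Gaussian CDFs evaluated in log space.
#'
#' `implicit_prob_right()` returns the posterior probability of category +1;
#' `implicit_decision()` returns the maximum-a-posteriori response, +1
#' (right) or -1 (left), with exact ties broken toward +1.
#'
#' @inheritParams likelihood_common
#' @return `implicit_prob_right()`: probabilities; `implicit_decision()`:
#'   integer responses in \{-1, +1\}.
#' @export
implicit_prob_right <- function(x_a, x_v, params, reliability) {
  s2a <- params$sigma_a^2
  s2v <- params$sigma_v[[reliability]]^2
  w1 <- post_common_from_logliks(
    log_lik_common(x_a, x_v, s2a, s2v, params),
    log_lik_separate(x_a, x_v, s2a, s2v, params), params$p_common)
  pd1 <- plogis_safe(logit_d_common(x_a, x_v, s2a, s2v, params))
  pd2 <- plogis_safe(logit_d_auditory(x_a, s2a, params))
  w1 * pd1 + (1 - w1) * pd2
}

#' @rdname implicit_prob_right
#' @export
implicit_decision <- function(x_a, x_v, params, reliability) {
  ifelse(implicit_prob_right(x_a, x_v, params, reliability) >= 0.5, 1L, -1L)
}

# log posterior odds of D=+1 within the common-cause branch
logit_d_common <- function(x_a, x_v, s2a, s2v, params) {
  s2ap <- params$sigma_a_prior^2
  s2vp <- params$sigma_v_prior^2
  v1 <- 1 / (1 / s2a + 1 / s2v)
  m1 <- v1 * (x_a / s2a + x_v / s2v)
  vp <- 1 / (1 / s2ap + 1 / s2vp)
  mp <- vp * (params$mu_a_prior / s2ap + params$mu_v_prior / s2vp)
  v_post <- 1 / (1 / v1 + 1 / vp)
  z1 <- (v_post * (m1 / v1 + mp / vp)) / sqrt(v_post)
  zp <- mp / sqrt(vp)
  stats::qlogis(params$p_choice_implicit) +
    stats::pnorm(z1, log.p = TRUE) - stats::pnorm(-z1, log.p = TRUE) -
    stats::pnorm(zp, log.p = TRUE) + stats::pnorm(-zp, log.p = TRUE)
}

# log posterior odds of D=+1 from the auditory cue alone (separate-cause
# branch of the implicit task, and the unisensory auditory observer)
logit_d_auditory <- function(x_a, s2a, params) {
  s2ap <- params$sigma_a_prior^2
  va <- 1 / (1 / s2a + 1 / s2ap)
  za <- (va * (x_a / s2a + params$mu_a_prior / s2ap)) / sqrt(va)
  zap <- params$mu_a_prior / params$sigma_a_prior
  stats::qlogis(params$p_choice_implicit) +
    stats::pnorm(za, log.p = TRUE) - stats::pnorm(-za, log.p = TRUE) -
    stats::pnorm(zap, log.p = TRUE) + stats::pnorm(-zap, log.p = TRUE)
}

# visual counterpart, for unisensory visual localization
logit_d_visual <- function(x_v, s2v, params) {
  s2vp <- params$sigma_v_prior^2
  vv <- 1 / (1 / s2v + 1 / s2vp)
  zv <- (vv * (x_v / s2v + params$mu_v_prior / s2vp)) / sqrt(vv)
  zvp <- params$mu_v_prior / params$sigma_v_prior
  stats::qlogis(params$p_choice_implicit) +
    stats::pnorm(zv, log.p = TRUE) - stats::pnorm(-zv, log.p = TRUE) -
    stats::pnorm(zvp, log.p = TRUE) + stats::pnorm(-zvp, log.p = TRUE)
}

plogis_safe <- function(l) {
  out <- stats::plogis(l)
  out[l == Inf] <- 1
  out[l == -Inf] <- 0
  out
}

#' Explicit (common-cause report) decision rule
#'
#' The observer reports "common source" (code 1) when
#' `L1 * p_combined > L2 * (1 - p_combined)`, where `L1`, `L2` are the
#' marginal likelihoods of the one- and two-cause structures and
#' `p_combined` is the single estimable mixture of the common-cause prior,
#' the explicit choice bias, and task learning. Ties go to "common".
#'
#' @inheritParams likelihood_common
#' @return Integer responses: 1 = common source, 2 = separate sources.
#' @export
explicit_decision <- function(x_a, x_v, params, reliability) {
  q <- params$p_combined
  n <- length(x_a)
  if (q >= 1) return(rep(1L, n))
  if (q <= 0) return(rep(2L, n))
  s2a <- params$sigma_a^2
  s2v <- params$sigma_v[[reliability]]^2
  common <- log(q) + log_lik_common(x_a, x_v, s2a, s2v, params) >=
    log1p(-q) + log_lik_separate(x_a, x_v, s2a, s2v, params)
  ifelse(common, 1L, 2L)
}

# cached 1-D Gauss-Hermite nodes (probabilists' transform applied later)
gh_cache <- new.env(parent = emptyenv())
gh_nodes <- function(order) {
  order <- as.integer(order)
  if (order < 3L) stop("quadrature order must be >= 3", call. = FALSE)
  key <- as.character(order)
  if (is.null(gh_cache[[key]])) {
    gh <- pracma::gaussHermite(order)
    gh_cache[[key]] <- list(u = gh$x, w = gh$w / sqrt(pi))
  }
  gh_cache[[key]]
}

#' Effective explicit-task mixture weight
#'
#' In the explicit task the common-cause prior `p_common`, the explicit
#' choice bias `p_choice_explicit`, and the task-learning parameter
#' `alpha_task` collapse into one estimable quantity `p_combined`:
#' the decision "common iff `L1 * p_combined > L2 * (1 - p_combined)`" is
#' equivalent to the observer's full posterior decision. With
#' `A = p_common (2 p_choice - 1) + alpha B` and
#' `D = (1 - p_common)(1 - 2 p_choice) + alpha B`, where
#' `B = p_common (1 - p_choice) + p_choice (1 - p_common)`,
#' `p_combined = A / (A + D)` clipped to \[0, 1\]. When `A + D = 0` the
#' decision is measurement-independent and the boundary value (0, 1, or 0.5
#' at an exact tie) is returned. None of the three components is separately
#' identifiable from explicit reports; this function exists for forward
#' exploration of the surface.
#'
#' `p_combined_from_criterion()` expresses the same decision as thresholding
#' the cause posterior at a criterion `t`:
#' `p_combined = (1 - t) p_common / ((1 - t) p_common + t (1 - p_common))`,
#' and `criterion_from_p_combined()` is its inverse in `t`.
#'
#' @param p_common Prior probability of a common cause, in \[0, 1\].
#' @param p_choice_explicit Explicit choice bias, in \[0, 1\].
#' @param alpha_task Task-learning weight, in \[0, 1\]: 0 = no learned link
#'   between report category and cause, 1 = report category equals cause.
#' @return `p_combined` in \[0, 1\] (or `t` in (0, 1) for the inverse).
#' @examples
#' p_combined_from_criterion(0.5, 0.3)  # unbiased criterion returns p_common
#' @export
p_combined_from_components <- function(p_common, p_choice_explicit,
                                       alpha_task) {
  b <- p_common * (1 - p_choice_explicit) +
    p_choice_explicit * (1 - p_common)
  a <- p_common * (2 * p_choice_explicit - 1) + alpha_task * b
  d <- (1 - p_common) * (1 - 2 * p_choice_explicit) + alpha_task * b
  out <- ifelse(a + d > 0, clip(a / (a + d), 0, 1),
                ifelse(a > d, 1, ifelse(a < d, 0, 0.5)))
  out
}

#' @rdname p_combined_from_components
#' @param t Decision criterion on the cause posterior, in (0, 1).
#' @export
p_combined_from_criterion <- function(t, p_common) {
  if (any(t <= 0 | t >= 1) || any(p_common <= 0 | p_common >= 1))
    stop("`t` and `p_common` must lie strictly inside (0, 1)", call. = FALSE)
  (1 - t) * p_common / ((1 - t) * p_common + t * (1 - p_common))
}

#' @rdname p_combined_from_components
#' @param p_combined Effective mixture weight, in (0, 1).
#' @export
criterion_from_p_combined <- function(p_combined, p_common) {
  if (any(p_combined <= 0 | p_combined >= 1) ||
      any(p_common <= 0 | p_common >= 1))
    stop("arguments must lie strictly inside (0, 1)", call. = FALSE)
  p_common * (1 - p_combined) /
    (p_common * (1 - p_combined) + p_combined * (1 - p_common))
}
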