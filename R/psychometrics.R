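#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood fit of
#' `P(right | x) = lapse_rate * lapse_bias + (1 - lapse_rate) * Phi((x - mu) / sigma)`
#' to per-location binomial response counts. `mu` is the bias (point of
#' subjective equality) and `sigma` the threshold (SD of the fitted
#' cumulative Gaussian; smaller = more precise). Optimization uses bounded
#' quasi-Newton iterations from several seeded starting points; ties between
#' converged starts are broken by lowest negative log-likelihood, then lowest
#' parameter norm.
#'
#' Data in which every response is identical carry no slope information; such
#' fits are returned with `degenerate = TRUE` and `NA` parameters instead of
#' silently extreme estimates.
#'
#' @param data A `data.frame` with columns `x` (stimulus location), `k`
#'   (number of positive/rightward responses) and `n` (trials); at least 3
#'   distinct locations with `n >= 1`.
#' @param lapse_mode `"rate_only"` (default; lapse bias fixed at 0.5),
#'   `"none"` (no lapses), or `"rate_and_bias"`.
#' @param n_starts Number of seeded multi-starts.
#' @param seed Seed for the start perturbations.
#' @return An object of class `psychometric_fit` with elements `mu`, `sigma`,
#'   `lapse_rate`, `lapse_bias`, `nll`, `r_squared`, `n_trials`,
#'   `degenerate`, `converged`.
#' @examples
#' d <- data.frame(x = -3:3, k = c(0, 1, 4, 8, 12, 14, 15), n = 15)
#' fit <- fit_cumulative_gaussian(d)
#' c(fit$mu, fit$sigma)
#' @export
fit_cumulative_gaussian <- function(data,
                                    lapse_mode = c("rate_only", "none",
                                                   "rate_and_bias"),
                                    n_starts = 10L, seed = 1L) {
  lapse_mode <- match.arg(lapse_mode)
  stopifnot(all(c("x", "k", "n") %in% names(data)))
  data <- data[data$n >= 1, ]
  if (length(unique(data$x)) < 3L)
    stop("need at least 3 distinct stimulus locations", call. = FALSE)
  if (any(data$k < 0 | data$k > data$n))
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  n_trials <- sum(data$n)
  if (sum(data$k) == 0L || sum(data$k) == n_trials) {
    out <- list(mu = NA_real_, sigma = NA_real_, lapse_rate = NA_real_,
                lapse_bias = NA_real_, nll = NA_real_, r_squared = NA_real_,
                n_trials = n_trials, lapse_mode = lapse_mode,
                degenerate = TRUE, converged = FALSE, data = data)
    class(out) <- "psychometric_fit"
    return(out)
  }

  rng <- max(diff(range(data$x)), 1e-3)
  # parameters: mu, log sigma, [qlogis(lapse/0.5)], [qlogis(bias)]
  n_par <- switch(lapse_mode, none = 2L, rate_only = 3L, rate_and_bias = 4L)
  unpack <- function(th) {
    lr <- if (n_par >= 3L) 0.5 * stats::plogis(th[3]) else 0
    lb <- if (n_par == 4L) stats::plogis(th[4]) else 0.5
    list(mu = th[1], sigma = exp(th[2]), lapse_rate = lr, lapse_bias = lb)
  }
  nll_fn <- function(th) {
    p <- unpack(th)
    pr <- p$lapse_rate * p$lapse_bias +
      (1 - p$lapse_rate) * stats::pnorm((data$x - p$mu) / p$sigma)
    pr <- clip(pr, 1e-9, 1 - 1e-9)
    -sum(data$k * log(pr) + (data$n - data$k) * log(1 - pr))
  }
  p_hat <- data$k / data$n
  mu0 <- stats::weighted.mean(data$x, data$n * p_hat * (1 - p_hat) + 1e-6)
  base <- c(mu0, log(rng / 4), stats::qlogis(0.04), 0)[seq_len(n_par)]
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(i) {
    if (i == 1L) base
    else base + stats::rnorm(n_par, 0, c(rng / 4, 0.7, 1, 1)[seq_len(n_par)])
  }))
  lower <- c(min(data$x) - 2 * rng, log(rng * 1e-3), -10, -10)[seq_len(n_par)]
  upper <- c(max(data$x) + 2 * rng, log(rng * 10), 10, 10)[seq_len(n_par)]
  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      stats::optim(clip(st, lower, upper), nll_fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e-8 / .Machine$double.eps)),
      error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || f$value < best$value - 1e-9 ||
        (abs(f$value - best$value) <= 1e-9 &&
         sum(f$par^2) < sum(best$par^2)))
      best <- f
  }
  if (is.null(best))
    stop("psychometric fit failed to converge from any start", call. = FALSE)
  p <- unpack(best$par)
  out <- list(mu = p$mu, sigma = p$sigma, lapse_rate = p$lapse_rate,
              lapse_bias = p$lapse_bias, nll = best$value,
              r_squared = NA_real_, n_trials = n_trials,
              lapse_mode = lapse_mode, degenerate = FALSE,
              converged = best$convergence == 0, data = data)
  class(out) <- "psychometric_fit"
  out$r_squared <- goodness_of_fit(out, data)
  out
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Degenerate psychometric data (all responses identical); no fit.\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Cumulative-Gaussian fit: mu = %.3f, sigma = %.3f (lapse %.3f/%.2f)\n",
    x$mu, x$sigma, x$lapse_rate, x$lapse_bias))
  cat(sprintf("  R^2 = %.3f on %d trials\n", x$r_squared, x$n_trials))
  invisible(x)
}

#' Predicted response probabilities of a psychometric fit
#'
#' @param object A `psychometric_fit`.
#' @param newdata Optional data frame with column `x`.
#' @param ... Unused.
#' @return Vector of predicted positive-response probabilities.
#' @export
predict.psychometric_fit <- function(object, newdata = NULL, ...) {
  x <- (newdata %||% object$data)$x
  object$lapse_rate * object$lapse_bias +
    (1 - object$lapse_rate) * stats::pnorm((x - object$mu) / object$sigma)
}

#' Variance-explained goodness of fit on per-condition proportions
#'
#' `R^2 = 1 - RSS / TSS` between the fitted response probabilities and the
#' observed per-location proportions. This is the quantity screened against
#' the 0.50 exclusion threshold for subjects whose reports do not modulate
#' with the stimulus.
#'
#' @param fit A `psychometric_fit` (from the same stimulus grid as `data`).
#' @param data Optional counts data frame (defaults to the fitted data).
#' @return The R-squared (can be negative for fits worse than the mean).
#' @export
goodness_of_fit <- function(fit, data = NULL) {
  data <- data %||% fit$data
  obs <- data$k / data$n
  pred <- predict(fit, data)
  rss <- sum((obs - pred)^2)
  tss <- sum((obs - mean(obs))^2)
  if (tss == 0) return(-Inf)
  1 - rss / tss
}

#' Gaussian fit to common-cause report proportions
#'
#' Least-squares fit of `p(delta) = amplitude * exp(-(delta - mean)^2 /
#' (2 width^2)) + baseline` to the proportion of common-source (or
#' synchronous) reports per disparity. By default the baseline is fixed at 0
#' (the descriptive three-parameter curve); [fit_gaussian_plus_bias()] holds
#' the Gaussian shape of a reference fit and frees only the additive
#' baseline, the functional-form alternative used to contrast groups.
#'
#' Fits whose `r_squared` falls below 0.5 are flagged (`flat = TRUE`),
#' mirroring the screening rule for subjects whose reports do not modulate
#' with disparity.
#'
#' @param prop_common A `data.frame` with columns `delta` and `prop` (and
#'   optionally `n`, used only by callers); at least 5 disparity levels.
#' @param n_starts,seed Multi-start control for the nonlinear least squares.
#' @return An object of class `gaussian_curve_fit` with `amplitude`, `mean`,
#'   `width`, `baseline`, `r_squared`, `flat`.
#' @examples
#' d <- data.frame(delta = seq(-24, 24, by = 6))
#' d$prop <- 0.8 * exp(-d$delta^2 / (2 * 15^2))
#' fit_gaussian_curve(d)$width
#' @export
fit_gaussian_curve <- function(prop_common, n_starts = 8L, seed = 1L) {
  stopifnot(all(c("delta", "prop") %in% names(prop_common)))
  d <- prop_common
  if (length(unique(d$delta)) < 5L)
    stop("need at least 5 disparity levels", call. = FALSE)
  rngx <- diff(range(d$delta))
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(i) {
    if (i == 1L)
      c(A = max(min(max(d$prop), 1), 0.05),
        m = d$delta[which.max(d$prop)], w = rngx / 4)
    else c(A = stats::runif(1, 0.1, 1), m = stats::runif(1, min(d$delta),
                                                         max(d$delta)),
           w = stats::runif(1, rngx / 20, rngx))
  }))
  best <- NULL
  for (st in starts) {
    f <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      prop ~ A * exp(-(delta - m)^2 / (2 * w^2)), data = d,
      start = as.list(st),
      lower = c(A = 0, m = min(d$delta) - rngx, w = rngx * 1e-3),
      upper = c(A = 1, m = max(d$delta) + rngx, w = rngx * 20),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::resid(f)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(rss = rss, par = stats::coef(f))
  }
  if (is.null(best))
    stop("Gaussian curve fit failed to converge", call. = FALSE)
  new_gaussian_curve_fit(best$par[["A"]], best$par[["m"]], best$par[["w"]],
                         baseline = 0, d)
}

new_gaussian_curve_fit <- function(amplitude, mean, width, baseline, d) {
  pred <- amplitude * exp(-(d$delta - mean)^2 / (2 * width^2)) + baseline
  tss <- sum((d$prop - base::mean(d$prop))^2)
  r2 <- if (tss == 0) -Inf else 1 - sum((d$prop - pred)^2) / tss
  out <- list(amplitude = amplitude, mean = mean, width = width,
              baseline = baseline, r_squared = r2, flat = r2 < 0.5,
              data = d)
  class(out) <- "gaussian_curve_fit"
  out
}

#' @export
print.gaussian_curve_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian curve: amplitude %.3f, mean %.2f, width %.2f, baseline %.3f\n",
    x$amplitude, x$mean, x$width, x$baseline))
  cat(sprintf("  R^2 = %.3f%s\n", x$r_squared,
              if (x$flat) "  [flat-report flag]" else ""))
  invisible(x)
}

#' @export
predict.gaussian_curve_fit <- function(object, newdata = NULL, ...) {
  delta <- (newdata %||% object$data)$delta
  object$amplitude * exp(-(delta - object$mean)^2 / (2 * object$width^2)) +
    object$baseline
}

#' @rdname fit_gaussian_curve
#' @param reference_fit A `gaussian_curve_fit` (typically from control-like
#'   data) whose amplitude, mean and width are held fixed.
#' @export
fit_gaussian_plus_bias <- function(prop_common, reference_fit) {
  stopifnot(inherits(reference_fit, "gaussian_curve_fit"),
            all(c("delta", "prop") %in% names(prop_common)))
  d <- prop_common
  shape <- reference_fit$amplitude *
    exp(-(d$delta - reference_fit$mean)^2 / (2 * reference_fit$width^2))
  b <- mean(d$prop - shape)  # least-squares additive bias, closed form
  new_gaussian_curve_fit(reference_fit$amplitude, reference_fit$mean,
                         reference_fit$width, baseline = b, d)
}

#' Nested polynomial regression of auditory bias against disparity
#'
#' Ordinary least squares of `bias = a0 + a1 d + a2 d^2 + a3 d^3` together
#' with its nested null, linear and quadratic submodels. The cubic term
#' captures saturation or reversal of the bias at large disparities (the
#' causal-inference signature); its contribution is summarized by the partial
#' R-squared `(RSS_quadratic - RSS_cubic) / RSS_quadratic`.
#'
#' @param bias_by_delta A `data.frame` with columns `delta` and `bias`
#'   (one row per disparity, typically per reliability); at least 5 distinct
#'   disparities.
#' @return An object of class `poly_regression_fit`: `coefficients`
#'   (a0..a3), `r_squared_by_order` (named `null`, `linear`, `quadratic`,
#'   `cubic`), `partial_r2_cubic`, and the per-order `rss`.
#' @examples
#' d <- data.frame(delta = c(-24, -12, -6, -3, 0, 3, 6, 12, 24))
#' d$bias <- 0.5 * d$delta - 5e-4 * d$delta^3
#' fit_cubic_regression(d)$partial_r2_cubic
#' @export
fit_cubic_regression <- function(bias_by_delta) {
  stopifnot(all(c("delta", "bias") %in% names(bias_by_delta)))
  d <- bias_by_delta
  if (anyNA(d$delta) || anyNA(d$bias))
    stop("disparities and biases must be non-missing", call. = FALSE)
  if (length(unique(d$delta)) < 5L)
    stop("need at least 5 distinct disparities", call. = FALSE)
  forms <- list(null = bias ~ 1, linear = bias ~ delta,
                quadratic = bias ~ delta + I(delta^2),
                cubic = bias ~ delta + I(delta^2) + I(delta^3))
  fits <- lapply(forms, stats::lm, data = d)
  if (any(is.na(stats::coef(fits$cubic))))
    stop("rank-deficient design: cubic model is not estimable", call. = FALSE)
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  tss <- sum((d$bias - mean(d$bias))^2)
  r2 <- if (tss == 0) rep(NA_real_, 4) else 1 - rss / tss
  names(r2) <- names(forms)
  cf <- stats::coef(fits$cubic)
  names(cf) <- c("a0", "a1", "a2", "a3")
  # a numerically exhausted quadratic residual leaves nothing for the cubic
  pr2 <- if (rss[["quadratic"]] <= 1e-10 * max(tss, 1)) 0
         else (rss[["quadratic"]] - rss[["cubic"]]) / rss[["quadratic"]]
  out <- list(coefficients = cf, r_squared_by_order = r2,
              partial_r2_cubic = pr2, rss = rss, models = fits)
  class(out) <- "poly_regression_fit"
  out
}

#' @export
print.poly_regression_fit <- function(x, ...) {
  cat("Nested polynomial regression of bias vs disparity\n")
  cat("  a0..a3 :", sprintf("%.4g", x$coefficients), "\n")
  cat("  R^2    :", sprintf("%s=%.3f", names(x$r_squared_by_order),
                            x$r_squared_by_order), "\n")
  cat(sprintf("  partial R^2 (cubic) = %.4f\n", x$partial_r2_cubic))
  invisible(x)
}

#' Per-condition response proportions of a response data set
#'
#' Utility used throughout the descriptive analyses: tabulates, for one
#' experiment's trials, the proportion of positive-code responses
#' (right / common / synchronous) per unique condition cell.
#'
#' @param data A response `data.frame` (schema of [write_response_csv()]).
#' @param by Character vector of grouping columns.
#' @param positive_code The response value counted as positive (+1 for
#'   localization tasks, 1 for explicit tasks).
#' @return A `data.frame` with the grouping columns plus `k`, `n`, `prop`.
#' @export
response_proportions <- function(data, by = c("delta", "reliability"),
                                 positive_code = 1L) {
  stopifnot(all(by %in% names(data)), "response" %in% names(data))
  key <- interaction(data[by], drop = TRUE, lex.order = TRUE)
  agg <- do.call(rbind, lapply(split(data, key), function(g) {
    cbind(g[1, by, drop = FALSE],
          data.frame(k = sum(g$response == positive_code), n = nrow(g)))
  }))
  agg$prop <- agg$k / agg$n
  rownames(agg) <- NULL
  agg[do.call(order, agg[by]), , drop = FALSE]
}
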