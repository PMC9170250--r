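#' Fitting configuration
#'
#' Controls the maximum-likelihood machinery: seeded multi-start
#' derivative-free optimization (Nelder-Mead on an unconstrained transform of
#' the parameters: log for SDs, logit for probabilities, logit of
#' `rate / 0.5` for the lapse rate) over the trial-level likelihood, with the
#' response probabilities computed by tensor-product Gauss-Hermite
#' quadrature.
#'
#' @param n_starts Number of seeded starting points (first start = `start`).
#' @param quad_order Gauss-Hermite order per dimension used inside the
#'   likelihood.
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @param reltol Relative convergence tolerance on the negative
#'   log-likelihood.
#' @param seed Seed for start perturbations.
#' @param start An [observer_params()] used as the first start and as the
#'   source of every non-free (fixed) parameter value.
#' @param free Character vector naming the free parameters, or `NULL` to let
#'   the fitter choose from the tasks present in the data (see
#'   [fit_subject()]).
#' @param n_boot Bootstrap replicates for 68% confidence intervals
#'   (0 = skip).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 20L, quad_order = 25L, maxit = 800L,
                       reltol = 1e-8, seed = 1L, start = observer_params(),
                       free = NULL, n_boot = 0L) {
  stopifnot(n_starts >= 1L, quad_order >= 3L)
  validate_observer_params(start)
  out <- list(n_starts = as.integer(n_starts),
              quad_order = as.integer(quad_order),
              maxit = as.integer(maxit), reltol = reltol,
              seed = as.integer(seed), start = start, free = free,
              n_boot = as.integer(n_boot))
  class(out) <- "fit_config"
  out
}

# ---- parameter vector <-> observer_params -----------------------------------

par_names_all <- c("sigma_a", "sigma_v_high", "sigma_v_medium", "sigma_v_low",
                   "sigma_a_prior", "sigma_v_prior", "mu_a_prior",
                   "mu_v_prior", "p_common", "p_choice_implicit",
                   "p_combined", "lapse_rate", "lapse_bias")

get_par <- function(params, nm) {
  switch(nm,
         sigma_v_high = params$sigma_v[["high"]],
         sigma_v_medium = params$sigma_v[["medium"]],
         sigma_v_low = params$sigma_v[["low"]],
         params[[nm]])
}

set_par <- function(params, nm, value) {
  if (startsWith(nm, "sigma_v_")) {
    params$sigma_v[[sub("sigma_v_", "", nm)]] <- value
  } else {
    params[[nm]] <- value
  }
  params
}

par_scale <- function(nm) {
  if (nm %in% c("mu_a_prior", "mu_v_prior")) return("identity")
  if (nm %in% c("p_common", "p_choice_implicit", "p_combined", "lapse_bias"))
    return("logit")
  if (nm == "lapse_rate") return("logit_half")
  "log"
}

to_theta <- function(params, free) {
  vapply(free, function(nm) {
    v <- get_par(params, nm)
    switch(par_scale(nm),
           identity = v,
           log = log(v),
           logit = stats::qlogis(clip(v, 1e-6, 1 - 1e-6)),
           logit_half = stats::qlogis(clip(v / 0.5, 1e-6, 1 - 1e-6)))
  }, numeric(1))
}

from_theta <- function(theta, free, base) {
  p <- base
  for (i in seq_along(free)) {
    nm <- free[i]
    v <- switch(par_scale(nm),
                identity = theta[[i]],
                log = exp(theta[[i]]),
                logit = stats::plogis(theta[[i]]),
                logit_half = 0.5 * stats::plogis(theta[[i]]))
    p <- set_par(p, nm, unname(v))
  }
  p
}

# ---- likelihood context -----------------------------------------------------

rel_levels <- c("high", "medium", "low")

# Tabulate, per unique design cell, the positive-response counts so that one
# likelihood evaluation is a handful of vectorized batch predictions.
build_nll_context <- function(data, quad_order) {
  stopifnot(all(c("experiment", "condition", "eps_a", "eps_v", "reliability",
                  "response") %in% names(data)))
  if (any(data$experiment %in% c("exp4", "exp5")))
    stop(paste("the trial-level causal-inference likelihood covers the",
               "spatial experiments only (exp1-exp3)"), call. = FALSE)
  # positive code is 1 in every task (+1 right; 1 common)
  pos <- data$response == 1L
  key <- paste(data$experiment, data$condition, data$eps_a, data$eps_v,
               data$reliability, sep = "|")
  cells <- do.call(rbind, lapply(split(seq_len(nrow(data)), key), function(i) {
    data.frame(experiment = data$experiment[i[1]],
               condition = data$condition[i[1]],
               eps_a = data$eps_a[i[1]], eps_v = data$eps_v[i[1]],
               reliability = data$reliability[i[1]],
               k = sum(pos[i]), n = length(i))
  }))
  rownames(cells) <- NULL
  cells$rel <- match(cells$reliability, rel_levels)
  block <- function(sel) {
    cc <- cells[sel, , drop = FALSE]
    if (!nrow(cc)) return(NULL)
    cc
  }
  list(
    aud = block(cells$condition == "auditory_only"),
    vis = block(cells$condition == "visual_only"),
    av_imp = block(cells$condition == "audio_visual" &
                     cells$experiment %in% c("exp1", "exp2")),
    av_exp = block(cells$condition == "audio_visual" &
                     cells$experiment == "exp3"),
    quad_order = quad_order, n_trials = nrow(data))
}

# per-cell lapse-adjusted response probabilities for every block of a context
cell_probs <- function(params, ctx) {
  lapse <- function(p_raw) params$lapse_rate * params$lapse_bias +
    (1 - params$lapse_rate) * p_raw
  out <- list()
  if (!is.null(ctx$aud)) {
    b <- ctx$aud
    t_a <- unisensory_threshold(params, "auditory", params$sigma_a^2)
    raw <- if (is.infinite(t_a)) rep(as.numeric(t_a < 0), nrow(b))
           else stats::pnorm((b$eps_a - t_a) / params$sigma_a)
    out$aud <- list(k = b$k, n = b$n, p = lapse(raw))
  }
  if (!is.null(ctx$vis)) {
    b <- ctx$vis
    raw <- numeric(nrow(b))
    for (r in unique(b$rel)) {
      sv <- params$sigma_v[[r]]
      t_v <- unisensory_threshold(params, "visual", sv^2)
      i <- b$rel == r
      raw[i] <- if (is.infinite(t_v)) as.numeric(t_v < 0)
                else stats::pnorm((b$eps_v[i] - t_v) / sv)
    }
    out$vis <- list(k = b$k, n = b$n, p = lapse(raw))
  }
  if (!is.null(ctx$av_imp)) {
    b <- ctx$av_imp
    raw <- resp_prob_implicit_batch(b$eps_a, b$eps_v, params$sigma_v[b$rel],
                                    params, ctx$quad_order)
    out$av_imp <- list(k = b$k, n = b$n, p = lapse(raw))
  }
  if (!is.null(ctx$av_exp)) {
    b <- ctx$av_exp
    raw <- resp_prob_explicit_batch(b$eps_a, b$eps_v, params$sigma_v[b$rel],
                                    params, ctx$quad_order)
    out$av_exp <- list(k = b$k, n = b$n, p = lapse(raw))
  }
  out
}

nll_from_context <- function(params, ctx) {
  blocks <- cell_probs(params, ctx)
  total <- 0
  for (bl in blocks) {
    p <- clip(bl$p, 1e-9, 1 - 1e-9)
    total <- total - sum(bl$k * log(p) + (bl$n - bl$k) * log(1 - p))
  }
  total
}

#' Trial-level negative log-likelihood of the causal-inference observer
#'
#' Sums, over the unique design cells of the data, the binomial negative
#' log-likelihood of the observed response counts under the model's
#' lapse-adjusted response probabilities: the implicit localization rule for
#' combined trials of the unisensory + fusion and implicit experiments, the
#' explicit rule for common-cause reports, and the single-cue localization
#' rule for unisensory trials. Probabilities are floored at 1e-9 to guard
#' against log-underflow.
#'
#' @param params An [observer_params()].
#' @param data A response `data.frame` from the spatial experiments
#'   (exp1-exp3).
#' @param quad_order Gauss-Hermite order per dimension.
#' @return The scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(params, data, quad_order = 25L) {
  validate_observer_params(params)
  nll_from_context(params, build_nll_context(data, quad_order))
}

# ---- model variants ---------------------------------------------------------

variant_levels <- c("full_CI", "alt_A_forced_fusion", "alt_B_no_fusion",
                    "alt_C_no_lapse_bias", "alt_D_choice_only")

apply_variant <- function(variant, free, start) {
  if (variant == "alt_A_forced_fusion") {
    start$p_common <- 1
    start$p_combined <- 1
    free <- setdiff(free, c("p_common", "p_combined"))
  } else if (variant == "alt_B_no_fusion") {
    start$p_common <- 0
    start$p_combined <- 0
    free <- setdiff(free, c("p_common", "p_combined"))
  } else if (variant == "alt_C_no_lapse_bias") {
    start$lapse_bias <- 0.5
    free <- setdiff(free, "lapse_bias")
  } else if (variant == "alt_D_choice_only") {
    free <- intersect(free, c("lapse_rate", "lapse_bias",
                              "p_choice_implicit"))
  }
  list(free = free, start = start)
}

default_free <- function(data) {
  free <- character(0)
  has_aud <- any(data$condition == "auditory_only") ||
    any(data$condition == "audio_visual")
  if (has_aud) free <- c(free, "sigma_a")
  for (r in rel_levels)
    if (any(data$reliability %in% r)) free <- c(free, paste0("sigma_v_", r))
  if (any(data$condition == "audio_visual" &
          data$experiment %in% c("exp1", "exp2")))
    free <- c(free, "p_common", "p_choice_implicit")
  if (any(data$experiment == "exp3")) free <- c(free, "p_combined")
  c(free, "lapse_rate", "lapse_bias")
}

cheap_hash <- function(data) {
  paste(nrow(data),
        round(sum(data$eps_a, na.rm = TRUE), 4),
        round(sum(data$eps_v, na.rm = TRUE), 4),
        sum(data$response == 1L), sum(data$response == -1L),
        sum(data$response == 2L), sep = "/")
}

#' Fit the causal-inference observer to one subject's data
#'
#' Maximum-likelihood estimation by seeded multi-start Nelder-Mead over an
#' unconstrained transform of the free parameters. The default free set is
#' chosen from the tasks present: sensory noise parameters for the
#' modalities/reliabilities observed (constrained chiefly by the unisensory
#' trials), `p_common` and `p_choice_implicit` when implicit audio-visual
#' trials are present, `p_combined` when explicit reports are present, and
#' the two lapse parameters. Natural-prior parameters stay at their `start`
#' values unless explicitly freed via `config$free`.
#'
#' Model variants: `full_CI` (all free), `alt_A_forced_fusion`
#' (`p_common = 1`: cues always fused), `alt_B_no_fusion` (`p_common = 0`:
#' cues never fused), `alt_C_no_lapse_bias` (`lapse_bias = 0.5`), and
#' `alt_D_choice_only` (only choice parameters free - lapse rate, lapse
#' bias, and `p_choice_implicit` for implicit data - with everything else
#' held at the `start` values, typically a reference fit of another group).
#'
#' @param data Response `data.frame` covering exp1 and/or exp2/exp3 trials.
#' @param variant One of `full_CI`, `alt_A_forced_fusion`, `alt_B_no_fusion`,
#'   `alt_C_no_lapse_bias`, `alt_D_choice_only`.
#' @param config A [fit_config()].
#' @return An object of class `fitted_model`: `params`, `variant`, `free`,
#'   `nll`, `aic` (`= 2 * n_free_params + 2 * nll`), `n_free_params`,
#'   `ci68` (when `config$n_boot > 0`), `start_nlls`, `converged`,
#'   `data_hash`, `n_trials`.
#' @export
fit_subject <- function(data, variant = "full_CI", config = fit_config()) {
  variant <- match.arg(variant, variant_levels)
  stopifnot(inherits(config, "fit_config"))
  ctx <- build_nll_context(data, config$quad_order)
  free <- config$free %||% default_free(data)
  if (variant == "alt_D_choice_only" && is.null(config$free))
    free <- default_free(data)  # then intersected below
  va <- apply_variant(variant, free, config$start)
  free <- va$free
  start <- va$start
  if (!length(free)) stop("variant leaves no free parameters", call. = FALSE)
  if (!all(free %in% par_names_all))
    stop("unknown free parameter name(s): ",
         paste(setdiff(free, par_names_all), collapse = ", "), call. = FALSE)

  obj <- function(theta) nll_from_context(from_theta(theta, free, start), ctx)
  theta0 <- to_theta(start, free)
  starts <- with_seed(config$seed, lapply(seq_len(config$n_starts),
    function(i) {
      if (i == 1L) theta0 else theta0 + stats::rnorm(length(free), 0, 0.8)
    }))
  best <- NULL
  start_nlls <- numeric(0)
  for (th in starts) {
    f <- tryCatch(
      stats::optim(th, obj, method = "Nelder-Mead",
                   control = list(maxit = config$maxit,
                                  reltol = config$reltol)),
      error = function(e) NULL)
    if (is.null(f)) next
    start_nlls <- c(start_nlls, f$value)
    if (is.null(best) || f$value < best$value - 1e-9 ||
        (abs(f$value - best$value) <= 1e-9 &&
         sum(f$par^2) < sum(best$par^2)))
      best <- f
  }
  if (is.null(best))
    stop("model fit failed to converge from any start", call. = FALSE)
  params_hat <- from_theta(best$par, free, start)
  out <- list(params = params_hat, variant = variant, free = free,
              nll = best$value,
              aic = 2 * length(free) + 2 * best$value,
              n_free_params = length(free), ci68 = NULL,
              start_nlls = start_nlls, converged = best$convergence == 0,
              data_hash = cheap_hash(data), n_trials = ctx$n_trials,
              quad_order = config$quad_order)
  class(out) <- "fitted_model"
  if (config$n_boot > 0L) {
    cfg_fast <- config
    cfg_fast$n_boot <- 0L
    cfg_fast$n_starts <- 1L
    cfg_fast$start <- params_hat
    out$ci68 <- bootstrap_ci(
      data, function(d) fitted_free_params(
        fit_subject(d, variant, cfg_fast)),
      level = 0.68, n_boot = config$n_boot, seed = config$seed)$intervals
  }
  out
}

fitted_free_params <- function(fit) {
  vapply(fit$free, function(nm) get_par(fit$params, nm), numeric(1))
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("Causal-inference model fit [%s]\n", x$variant))
  cat(sprintf("  NLL = %.2f, AIC = %.2f (%d free params, %d trials)\n",
              x$nll, x$aic, x$n_free_params, x$n_trials))
  est <- fitted_free_params(x)
  cat("  ", paste(sprintf("%s = %.3g", names(est), est), collapse = ", "),
      "\n")
  invisible(x)
}

#' Fit the model to a pooled (aggregate) cohort
#'
#' Pools all trials of the cohort (optionally one group) into a single
#' aggregate subject and fits it exactly as [fit_subject()] does. Confidence
#' intervals, when requested, resample whole subjects rather than trials.
#'
#' @param cohort An `av_cohort` from [make_cohort()], or a list of response
#'   data frames.
#' @param variant,config As in [fit_subject()].
#' @param group Optional group label to pool.
#' @return A `fitted_model`.
#' @export
fit_aggregate <- function(cohort, variant = "full_CI", config = fit_config(),
                          group = NULL) {
  pooled <- if (inherits(cohort, "av_cohort")) pool_cohort(cohort, group)
            else do.call(rbind, cohort)
  n_boot <- config$n_boot
  config$n_boot <- 0L
  fit <- fit_subject(pooled, variant, config)
  if (n_boot > 0L && inherits(cohort, "av_cohort")) {
    cfg_fast <- config
    cfg_fast$n_starts <- 1L
    cfg_fast$start <- fit$params
    fit$ci68 <- bootstrap_ci(
      cohort, function(co) fitted_free_params(
        fit_aggregate(co, variant, cfg_fast, group = group)),
      level = 0.68, n_boot = n_boot, seed = config$seed)$intervals
  }
  fit
}

#' Rank fitted models by AIC
#'
#' @param fits A list of `fitted_model` objects fit to the same data.
#' @return A `data.frame` with `variant`, `n_free_params`, `nll`, `aic` and
#'   `delta_aic` (relative to the best model), sorted best-first.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "fitted_model")))
  hashes <- vapply(fits, `[[`, character(1), "data_hash")
  if (length(unique(hashes)) != 1L)
    stop("models were fit to different data sets", call. = FALSE)
  tab <- data.frame(
    variant = vapply(fits, `[[`, character(1), "variant"),
    n_free_params = vapply(fits, `[[`, numeric(1), "n_free_params"),
    nll = vapply(fits, `[[`, numeric(1), "nll"),
    aic = vapply(fits, `[[`, numeric(1), "aic"))
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab[order(tab$aic), , drop = FALSE]
}

#' Explainable variance explained (EVE)
#'
#' Goodness of fit for binomial condition-level data that discounts the
#' variance attributable to sampling noise: with per-condition observed
#' proportions `p_hat`, model predictions `p`, and mean binomial noise
#' variance `v_bar = mean(p_hat (1 - p_hat) / n)`,
#' `EVE = 1 - (MSE_model - v_bar) / (Var_data - v_bar)`, reported clipped to
#' at most 1. A saturated model scores 1; predicting the grand mean scores
#' about 0. When the data variance does not exceed the noise floor
#' (`Var_data <= v_bar`) the quantity is undefined and `NA` is returned with
#' a warning.
#'
#' @param fit A `fitted_model` (or bare [observer_params()]).
#' @param data Response data grouped into conditions (exp1-exp3 trials).
#' @param quad_order Quadrature order for the model predictions.
#' @return The EVE value in `(-Inf, 1]`, or `NA` if undefined.
#' @export
explainable_variance_explained <- function(fit, data, quad_order = 25L) {
  params <- if (inherits(fit, "fitted_model")) fit$params else fit
  validate_observer_params(params)
  blocks <- cell_probs(params, build_nll_context(data, quad_order))
  k <- unlist(lapply(blocks, `[[`, "k"))
  n <- unlist(lapply(blocks, `[[`, "n"))
  p <- unlist(lapply(blocks, `[[`, "p"))
  eve_from_proportions(k, n, p)
}

#' @rdname explainable_variance_explained
#' @param k,n Per-condition positive-response counts and trial counts.
#' @param p Per-condition model-predicted probabilities.
#' @export
eve_from_proportions <- function(k, n, p) {
  stopifnot(length(k) == length(n), length(n) == length(p), length(k) >= 2L,
            all(n >= 1))
  p_hat <- k / n
  v_bar <- mean(p_hat * (1 - p_hat) / n)
  var_data <- mean((p_hat - mean(p_hat))^2)
  if (var_data <= v_bar) {
    warning("data variance does not exceed the binomial noise floor; ",
            "EVE undefined")
    return(NA_real_)
  }
  mse <- mean((p_hat - p)^2)
  min(1, 1 - (mse - v_bar) / (var_data - v_bar))
}

#' Seeded nonparametric bootstrap confidence intervals
#'
#' Percentile intervals from resampling the data with replacement: trials
#' (stratified within subject) when `data` is a response data frame, whole
#' subjects when `data` is an `av_cohort`. The same resamples serve every
#' requested level, so narrower levels are nested inside wider ones.
#'
#' @param data A response `data.frame` or an `av_cohort`.
#' @param fit_fn Function mapping a resampled data set to a named numeric
#'   vector of estimates.
#' @param level Confidence level(s), e.g. `0.68` or `c(0.68, 0.95)`.
#' @param n_boot Number of bootstrap replicates (>= 100 recommended for
#'   reported intervals).
#' @param seed Integer seed.
#' @return A list with `draws` (replicate x parameter matrix) and
#'   `intervals` (a `data.frame` with `parameter`, `level`, `lower`,
#'   `upper`).
#' @export
bootstrap_ci <- function(data, fit_fn, level = 0.68, n_boot = 200L,
                         seed = 1L) {
  stopifnot(all(level > 0 & level < 1), n_boot >= 1L)
  resample <- if (inherits(data, "av_cohort")) {
    function() {
      idx <- sample.int(length(data), replace = TRUE)
      out <- data[idx]
      class(out) <- "av_cohort"
      out
    }
  } else {
    function() {
      idx <- unlist(lapply(split(seq_len(nrow(data)), data$subject_id %||%
                                   rep(1L, nrow(data))),
                           function(i) sample(i, replace = TRUE)))
      data[idx, , drop = FALSE]
    }
  }
  draws <- with_seed(seed, {
    rows <- lapply(seq_len(n_boot), function(b) fit_fn(resample()))
    do.call(rbind, rows)
  })
  if (is.null(colnames(draws)))
    colnames(draws) <- paste0("par", seq_len(ncol(draws)))
  ints <- do.call(rbind, lapply(level, function(lv) {
    lo <- apply(draws, 2, stats::quantile, probs = (1 - lv) / 2, names = FALSE)
    hi <- apply(draws, 2, stats::quantile, probs = 1 - (1 - lv) / 2,
                names = FALSE)
    data.frame(parameter = colnames(draws), level = lv, lower = lo,
               upper = hi, row.names = NULL)
  }))
  list(draws = draws, intervals = ints)
}

#' Simulate-and-refit parameter recovery study
#'
#' Repeatedly simulates an observer with known parameters on the given
#' schedules, refits the model, and summarizes estimation bias and RMSE per
#' free parameter. This is the package's primary self-check that the fitting
#' machinery can recover the generative parameters at realistic trial
#' counts.
#'
#' @param true_params The generating [observer_params()].
#' @param schedules A list of schedule data frames (e.g.
#'   `list(make_schedule_exp1(1), make_schedule_exp2(1))`).
#' @param n_reps Number of simulate-fit replicates (>= 1).
#' @param seed Integer master seed.
#' @param config A [fit_config()] used for every refit.
#' @return A `data.frame` with one row per recovered parameter: `parameter`,
#'   `true`, `mean_est`, `bias`, `rmse`; replicate-level estimates are
#'   attached as attribute `"draws"`.
#' @export
parameter_recovery_report <- function(true_params, schedules, n_reps = 20L,
                                      seed = 1L, config = fit_config()) {
  stopifnot(n_reps >= 1L)
  seed_tbl <- with_seed(seed, matrix(sample.int(536870912L,
                                                n_reps *
                                                  length(schedules)),
                                     nrow = n_reps))
  draws <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    dat <- do.call(rbind, lapply(seq_along(schedules), function(j)
      simulate_observer(schedules[[j]], true_params,
                        seed = seed_tbl[r, j])))
    fitted_free_params(fit_subject(dat, "full_CI", config))
  }))
  truth <- vapply(colnames(draws), function(nm) get_par(true_params, nm),
                  numeric(1))
  est <- colMeans(draws)
  out <- data.frame(parameter = colnames(draws), true = truth,
                    mean_est = est, bias = est - truth,
                    rmse = sqrt(colMeans(sweep(draws, 2, truth)^2)),
                    row.names = NULL)
  attr(out, "draws") <- draws
  out
}

#' Serialize a fitted model to JSON
#'
#' @param fit A `fitted_model`.
#' @param path Optional file path.
#' @return The JSON string (invisibly when written to file).
#' @export
fitted_model_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fitted_model"))
  x <- list(variant = fit$variant, free = fit$free,
            estimates = as.list(fitted_free_params(fit)),
            params = {
              p <- unclass(fit$params)
              p$sigma_v <- as.list(p$sigma_v)
              p
            },
            nll = fit$nll, aic = fit$aic,
            n_free_params = fit$n_free_params, n_trials = fit$n_trials,
            quad_order = fit$quad_order, converged = fit$converged,
            ci68 = fit$ci68)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
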