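#' Simulate observer responses for a trial schedule
#'
#' Draws noisy measurements for every trial of a schedule from
#' [make_schedule_exp1()] ... [make_schedule_exp4()] and applies the
#' matching decision rule of the generative model: the unisensory or implicit
#' localization rule for the unisensory + fusion and implicit
#' causal-inference experiments, the explicit common-cause rule for the
#' explicit spatial experiment, and the descriptive Gaussian synchrony curve
#' for the temporal experiment. Afterward, with probability `lapse_rate`, the
#' response is replaced by a coin flip landing on the positive code with
#' probability `lapse_bias`.
#'
#' Response coding: localization tasks +1 (right) / -1 (left); explicit
#' spatial task 1 (common) / 2 (separate); temporal task 1 (synchronous) /
#' 2 (asynchronous).
#'
#' @param schedule A schedule `data.frame` (exp1-exp4; the heading /
#'   object-motion experiment has no observer model and is rejected).
#' @param params An [observer_params()] object.
#' @param seed Integer seed for measurement noise and lapses.
#' @param subject_id,group Labels stored with the responses.
#' @return The schedule with `response`, `subject_id` and `group` columns;
#'   the generating parameters are attached as attribute `"params"`.
#' @examples
#' rd <- simulate_observer(make_schedule_exp2(1), observer_params(), seed = 1)
#' table(rd$response)
#' @export
simulate_observer <- function(schedule, params, seed = 0L,
                              subject_id = "synthetic_01",
                              group = "synthetic") {
  validate_observer_params(params)
  exp_id <- unique(schedule$experiment)
  if (any(exp_id == "exp5"))
    stop("no observer model exists for the heading/object-motion experiment",
         call. = FALSE)
  n <- nrow(schedule)
  response <- integer(n)
  with_seed(seed, {
    for (ex in unique(schedule$experiment)) {
      if (ex == "exp4") {
        i <- which(schedule$experiment == "exp4")
        p_raw <- params$sync_amplitude *
          exp(-(schedule$delta[i] - params$sync_mean)^2 /
                (2 * params$sync_width^2))
        p <- params$lapse_rate * params$lapse_bias +
          (1 - params$lapse_rate) * p_raw
        response[i] <- ifelse(stats::runif(length(i)) < p, 1L, 2L)
        next
      }
      for (rel in c(NA_character_, av_conventions()$reliabilities)) {
        i <- which(schedule$experiment == ex &
                     (is.na(schedule$reliability) == is.na(rel)) &
                     (is.na(rel) | schedule$reliability %in% rel))
        if (!length(i)) next
        cond <- schedule$condition[i]
        resp <- integer(length(i))
        ia <- cond == "auditory_only"
        if (any(ia)) {
          xa <- stats::rnorm(sum(ia), schedule$eps_a[i][ia], params$sigma_a)
          resp[ia] <- ifelse(logit_d_auditory(xa, params$sigma_a^2,
                                              params) >= 0, 1L, -1L)
        }
        iv <- cond == "visual_only"
        if (any(iv)) {
          sv <- params$sigma_v[[rel]]
          xv <- stats::rnorm(sum(iv), schedule$eps_v[i][iv], sv)
          resp[iv] <- ifelse(logit_d_visual(xv, sv^2, params) >= 0, 1L, -1L)
        }
        ib <- cond == "audio_visual"
        if (any(ib)) {
          xa <- stats::rnorm(sum(ib), schedule$eps_a[i][ib], params$sigma_a)
          xv <- stats::rnorm(sum(ib), schedule$eps_v[i][ib],
                             params$sigma_v[[rel]])
          resp[ib] <- if (ex == "exp3")
            explicit_decision(xa, xv, params, rel)
          else implicit_decision(xa, xv, params, rel)
        }
        response[i] <- resp
      }
    }
    # lapse overwrite (exp4 already folds the lapse into its curve)
    not4 <- schedule$experiment != "exp4"
    lapse <- not4 & stats::runif(n) < params$lapse_rate
    if (any(lapse)) {
      pos <- stats::runif(sum(lapse)) < params$lapse_bias
      neg_code <- ifelse(schedule$experiment[lapse] == "exp3", 2L, -1L)
      response[lapse] <- ifelse(pos, 1L, neg_code)
    }
  })
  out <- schedule
  out$response <- response
  out$subject_id <- subject_id
  out$group <- group
  attr(out, "params") <- params
  out
}

#' Specification of a synthetic cohort
#'
#' Describes the per-group distributions from which subject-level observer
#' parameters are drawn: each entry is a truncated normal with fields `mean`,
#' `sd`, `lo`, `hi`. Defaults encode a neurotypical-like control group and an
#' ASD-like group whose common-cause prior is three times larger on average
#' (the implicit-task signature), whose explicit mixture weight `p_combined`
#' is lower (the explicit compensation signature), and whose synchrony curve
#' has lower amplitude and larger width.
#'
#' @param control,asd Named lists of distribution entries; entries given
#'   here override the defaults (see the source for the full set).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(control = list(), asd = list()) {
  tn <- function(mean, sd, lo, hi) list(mean = mean, sd = sd, lo = lo, hi = hi)
  base <- list(
    sigma_a        = tn(4.76, 0.8, 1.5, 12),
    sigma_v_high   = tn(1.10, 0.2, 0.4, 3),
    sigma_v_medium = tn(4.76, 1.0, 1.5, 12),  # patch size varies by subject
    sigma_v_low    = tn(13.96, 2.5, 6, 25),
    p_choice_implicit = tn(0.5, 0.03, 0.3, 0.7),
    lapse_rate     = tn(0.03, 0.02, 0, 0.15),
    lapse_bias     = tn(0.5, 0.05, 0.2, 0.8),
    sync_mean      = tn(0, 15, -100, 100)
  )
  ctl <- utils::modifyList(c(base, list(
    p_common       = tn(0.25, 0.08, 0.02, 0.98),
    p_combined     = tn(0.60, 0.08, 0.02, 0.98),
    sync_amplitude = tn(0.98, 0.01, 0.5, 1),
    sync_width     = tn(171.68, 35, 50, 900)
  )), control)
  asd_ <- utils::modifyList(c(base, list(
    p_common       = tn(0.75, 0.08, 0.02, 0.98),
    p_combined     = tn(0.40, 0.10, 0.02, 0.98),
    sync_amplitude = tn(0.83, 0.04, 0.3, 1),
    sync_width     = tn(363, 70, 50, 1200)
  )), asd)
  out <- list(control = ctl, asd = asd_)
  class(out) <- "cohort_spec"
  validate_cohort_spec(out)
  out
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  for (g in c("control", "asd")) for (nm in names(spec[[g]])) {
    e <- spec[[g]][[nm]]
    if (!all(c("mean", "sd", "lo", "hi") %in% names(e)) ||
        e$sd < 0 || e$lo > e$hi || e$mean < e$lo || e$mean > e$hi)
      stop(sprintf("invalid cohort_spec entry '%s' in group '%s'", nm, g),
           call. = FALSE)
  }
  invisible(spec)
}

#' @rdname cohort_spec
#' @param spec A `cohort_spec` object.
#' @param path Optional file path for the JSON.
#' @export
cohort_spec_to_json <- function(spec, path = NULL) {
  validate_cohort_spec(spec)
  js <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname cohort_spec
#' @param json A JSON string or file path from [cohort_spec_to_json()].
#' @export
cohort_spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  cohort_spec(control = x$control, asd = x$asd)
}

rtruncnorm1 <- function(e) {
  if (e$sd == 0) return(e$mean)
  u <- stats::runif(1, stats::pnorm(e$lo, e$mean, e$sd),
                    stats::pnorm(e$hi, e$mean, e$sd))
  stats::qnorm(u, e$mean, e$sd)
}

draw_subject_params <- function(group_spec) {
  d <- lapply(group_spec, rtruncnorm1)
  observer_params(
    sigma_a = d$sigma_a,
    sigma_v = c(high = d$sigma_v_high, medium = d$sigma_v_medium,
                low = d$sigma_v_low),
    p_common = d$p_common, p_choice_implicit = d$p_choice_implicit,
    p_combined = d$p_combined,
    lapse_rate = d$lapse_rate, lapse_bias = d$lapse_bias,
    sync_amplitude = d$sync_amplitude, sync_mean = d$sync_mean,
    sync_width = d$sync_width)
}

#' Simulate a synthetic cohort
#'
#' Samples per-subject observer parameters from the group distributions of a
#' [cohort_spec()] and simulates every requested experiment for every
#' subject. Fully deterministic given `seed`.
#'
#' @param n_control,n_asd Numbers of subjects per group (>= 0).
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed.
#' @param experiments Character subset of `c("exp1","exp2","exp3","exp4")`.
#' @return A list of class `av_cohort`; each element is a list with `data`
#'   (all experiments row-bound), `params` (true generating parameters),
#'   `subject_id` and `group`.
#' @export
make_cohort <- function(n_control, n_asd, spec = cohort_spec(), seed = 0L,
                        experiments = c("exp1", "exp2")) {
  stopifnot(n_control >= 0, n_asd >= 0)
  validate_cohort_spec(spec)
  experiments <- match.arg(experiments, c("exp1", "exp2", "exp3", "exp4"),
                           several.ok = TRUE)
  gens <- list(exp1 = make_schedule_exp1, exp2 = make_schedule_exp2,
               exp3 = make_schedule_exp3, exp4 = make_schedule_exp4)
  groups <- rep(c("control", "asd"), c(n_control, n_asd))
  out <- vector("list", length(groups))
  if (!length(groups)) {
    class(out) <- "av_cohort"
    return(out)
  }
  # per-subject sub-seeds drawn under the master seed (stays within integer
  # range for any master seed)
  seed_tbl <- with_seed(seed, matrix(sample.int(536870912L,
                                                2L * length(groups)),
                                     ncol = 2L))
  for (k in seq_along(groups)) {
    g <- groups[k]
    pars <- with_seed(seed_tbl[k, 1L], draw_subject_params(spec[[g]]))
    dat <- do.call(rbind, lapply(seq_along(experiments), function(j) {
      ex <- experiments[j]
      simulate_observer(gens[[ex]](seed_tbl[k, 1L] + j),
                        pars, seed = seed_tbl[k, 2L] + j)
    }))
    id <- sprintf("%s_%02d", g, sum(groups[seq_len(k)] == g))
    dat$subject_id <- id
    dat$group <- g
    out[[k]] <- list(data = dat, params = pars, subject_id = id, group = g)
  }
  class(out) <- "av_cohort"
  out
}

#' Pool the trials of a cohort (or a subset) into one aggregate data set
#'
#' @param cohort An `av_cohort` from [make_cohort()].
#' @param group Optional group label to filter on.
#' @return A single `data.frame` of trials.
#' @export
pool_cohort <- function(cohort, group = NULL) {
  keep <- if (is.null(group)) cohort
          else cohort[vapply(cohort, function(s) s$group == group, logical(1))]
  if (!length(keep)) stop("no subjects selected", call. = FALSE)
  do.call(rbind, lapply(keep, `[[`, "data"))
}
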