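#' Generative observer parameters
#'
#' Bundles every parameter of the causal-inference ideal observer: sensory
#' noise (auditory, and visual per reliability level), the Gaussian natural
#' priors over unisensory locations, the inference parameters (`p_common` for
#' implicit localization, `p_combined` for explicit common-cause reports), the
#' stimulus-independent choice and lapse parameters, and the descriptive
#' synchrony-curve parameters used to generate temporal-disparity data.
#'
#' Default values describe a plausible neurotypical adolescent observer:
#' auditory noise matches the medium visual reliability (the design matched
#' these on purpose), visual noise per reliability follows the group
#' unisensory thresholds (1.10, 4.76, 13.96 degrees), natural priors are
#' broad and centered at straight ahead, and lapses are rare and unbiased.
#'
#' @param sigma_a Auditory sensory noise SD, degrees (> 0).
#' @param sigma_v Named numeric vector of visual noise SDs, degrees, with
#'   names `high`, `medium`, `low`.
#' @param mu_a_prior,mu_v_prior Means of the natural location priors, degrees.
#' @param sigma_a_prior,sigma_v_prior SDs of the natural location priors (> 0).
#' @param p_common Prior probability that the two cues share one cause.
#' @param p_choice_implicit Prior bias toward responding "right" in the
#'   implicit localization task.
#' @param p_combined Effective mixture weight of the explicit common-cause
#'   decision rule (combines `p_common`, explicit choice bias and task
#'   learning; see [p_combined_from_components()]).
#' @param lapse_rate Probability of a stimulus-independent response, in
#'   \[0, 1\] for simulation; model fits bound it at 0.5.
#' @param lapse_bias Probability that a lapse produces the positive response
#'   code (right / common / synchronous).
#' @param sync_amplitude,sync_mean,sync_width Amplitude, center (ms) and SD
#'   (ms) of the descriptive Gaussian synchrony-report curve used to simulate
#'   the temporal experiment.
#' @return An object of class `observer_params`.
#' @examples
#' p <- observer_params(p_common = 0.5)
#' p$sigma_v[["low"]]
#' @export
observer_params <- function(sigma_a = 4.76,
                            sigma_v = c(high = 1.10, medium = 4.76, low = 13.96),
                            mu_a_prior = 0, sigma_a_prior = 30,
                            mu_v_prior = 0, sigma_v_prior = 30,
                            p_common = 0.25,
                            p_choice_implicit = 0.5,
                            p_combined = 0.6,
                            lapse_rate = 0.02, lapse_bias = 0.5,
                            sync_amplitude = 0.98, sync_mean = 0,
                            sync_width = 171.68) {
  sigma_v <- unlist(sigma_v)
  if (!all(c("high", "medium", "low") %in% names(sigma_v)))
    stop("`sigma_v` must be named with high/medium/low", call. = FALSE)
  sigma_v <- sigma_v[c("high", "medium", "low")]
  p <- list(sigma_a = sigma_a, sigma_v = sigma_v,
            mu_a_prior = mu_a_prior, sigma_a_prior = sigma_a_prior,
            mu_v_prior = mu_v_prior, sigma_v_prior = sigma_v_prior,
            p_common = p_common, p_choice_implicit = p_choice_implicit,
            p_combined = p_combined,
            lapse_rate = lapse_rate, lapse_bias = lapse_bias,
            sync_amplitude = sync_amplitude, sync_mean = sync_mean,
            sync_width = sync_width)
  class(p) <- "observer_params"
  validate_observer_params(p)
  p
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Causal-inference observer parameters\n")
  cat(sprintf("  sensory : sigma_a = %.3g; sigma_v = %.3g/%.3g/%.3g (h/m/l)\n",
              x$sigma_a, x$sigma_v[["high"]], x$sigma_v[["medium"]],
              x$sigma_v[["low"]]))
  cat(sprintf("  priors  : a ~ N(%.3g, %.3g^2); v ~ N(%.3g, %.3g^2)\n",
              x$mu_a_prior, x$sigma_a_prior, x$mu_v_prior, x$sigma_v_prior))
  cat(sprintf("  inference: p_common = %.3g; p_combined = %.3g\n",
              x$p_common, x$p_combined))
  cat(sprintf("  choice  : p_choice = %.3g; lapse rate %.3g, bias %.3g\n",
              x$p_choice_implicit, x$lapse_rate, x$lapse_bias))
  invisible(x)
}

validate_observer_params <- function(p) {
  stopifnot(inherits(p, "observer_params"))
  pos <- c(p$sigma_a, p$sigma_v, p$sigma_a_prior, p$sigma_v_prior,
           p$sync_width)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("all noise/prior/width SDs must be finite and > 0", call. = FALSE)
  for (nm in c("p_common", "p_choice_implicit", "p_combined", "lapse_bias",
               "sync_amplitude"))
    stopifnot_scalar_prob(p[[nm]], nm)
  # the generator admits any lapse probability; fits bound it at 0.5
  stopifnot_scalar_prob(p$lapse_rate, "lapse_rate")
  invisible(p)
}

#' Serialize observer parameters to and from JSON
#'
#' @param params An `observer_params` object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `params_to_json()` returns a JSON string (invisibly, if written to
#'   a file); `params_from_json()` returns an `observer_params` object.
#' @export
params_to_json <- function(params, path = NULL) {
  validate_observer_params(params)
  x <- unclass(params)
  x$sigma_v <- as.list(x$sigma_v)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname params_to_json
#' @param json A JSON string or path to a JSON file written by
#'   [params_to_json()].
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$sigma_v <- unlist(x$sigma_v)
  do.call(observer_params, x)
}
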