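#' Forced-fusion (maximum-likelihood estimation) predictions
#'
#' Under optimal cue combination, two cues with unisensory thresholds
#' `sigma_a` and `sigma_v` fuse into an estimate with threshold
#' `sigma_com = sqrt(sigma_a^2 sigma_v^2 / (sigma_a^2 + sigma_v^2))`, each
#' cue weighted by its inverse variance:
#' `w_v = (1/sigma_v^2) / (1/sigma_v^2 + 1/sigma_a^2)` and `w_a = 1 - w_v`.
#' (The combined threshold is the square root of the usual harmonic-variance
#' expression; the variance form is sometimes printed without the root, which
#' is dimensionally a variance, not a threshold.)
#'
#' @param sigma_a,sigma_v Unisensory discrimination thresholds, degrees (> 0).
#'   Vectorized.
#' @return `predict_combined_threshold()`: the predicted combined threshold
#'   `sigma_com`; `predict_visual_weight()`: the predicted visual weight
#'   `w_v` in \[0, 1\].
#' @examples
#' predict_combined_threshold(2, 2)          # sigma / sqrt(2)
#' predict_visual_weight(4.76, 1.10)         # reliable vision dominates
#' @export
predict_combined_threshold <- function(sigma_a, sigma_v) {
  if (any(sigma_a <= 0) || any(sigma_v <= 0))
    stop("thresholds must be > 0", call. = FALSE)
  sqrt(sigma_a^2 * sigma_v^2 / (sigma_a^2 + sigma_v^2))
}

#' @rdname predict_combined_threshold
#' @export
predict_visual_weight <- function(sigma_a, sigma_v) {
  if (any(sigma_a <= 0) || any(sigma_v <= 0))
    stop("thresholds must be > 0", call. = FALSE)
  (1 / sigma_v^2) / (1 / sigma_v^2 + 1 / sigma_a^2)
}

#' Measured visual weight from cue-conflict points of subjective equality
#'
#' In conflict trials the cues straddle the mean stimulus location at
#' `mean +/- delta/2` (auditory at `+delta/2`). A fused percept with visual
#' weight `w_v` then sits at `mean + (1 - 2 w_v) delta / 2`, so the
#' psychometric function over mean location has its PSE at
#' `mu = (2 w_v - 1) delta / 2`. Contrasting the PSEs measured at `+delta`
#' and `-delta` eliminates any stimulus-independent bias and yields
#' `w_v = 1/2 + (mu_plus - mu_minus) / (2 delta)`.
#'
#' Estimates falling outside \[0, 1\] (possible with noisy PSEs) are clipped
#' and flagged via the `"clipped"` attribute.
#'
#' @param mu_plus,mu_minus PSEs (degrees, against mean stimulus location) of
#'   the psychometric functions at disparity `+delta` and `-delta`.
#' @param delta The positive conflict size, degrees (non-zero).
#' @return Measured visual weight in \[0, 1\] with attribute `clipped`.
#' @examples
#' measured_visual_weight(3, -3, 6)   # full visual capture -> 1
#' @export
measured_visual_weight <- function(mu_plus, mu_minus, delta) {
  if (any(delta == 0)) stop("`delta` must be non-zero", call. = FALSE)
  w <- 0.5 + (mu_plus - mu_minus) / (2 * delta)
  out <- clip(w, 0, 1)
  attr(out, "clipped") <- w != out
  out
}
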