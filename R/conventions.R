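#' Sign and design conventions
#'
#' All spatial quantities are in degrees of visual angle with positive values
#' to the observer's right. Spatial disparity is defined as
#' `delta = eps_a - eps_v` (auditory minus visual location), so positive delta
#' means the auditory stimulus lies to the right of the visual one. Temporal
#' disparity (the synchrony-judgment experiment) is in milliseconds with
#' positive delta meaning the visual stimulus led the auditory one.
#'
#' In cue-conflict trials of the unisensory + fusion experiment the two cues
#' straddle a mean stimulus location at `mean +/- delta/2` (auditory at
#' `mean + delta/2`, visual at `mean - delta/2`). In the implicit and explicit
#' causal-inference experiments the auditory cue sits on a speaker location
#' and the visual cue at `speaker - delta`.
#'
#' `av_conventions()` returns these constants (stimulus grids, disparity sets,
#' reliability levels, repetition counts) as a list so that every schedule
#' generator and model routine draws from one place.
#'
#' @return Named list of design constants.
#' @export
av_conventions <- function() {
  list(
    reliabilities = c("high", "medium", "low"),
    # unisensory + fusion experiment (exp1)
    exp1_aud_locations = c(-9, -6, -3, 0, 3, 6, 9),
    # 14 visual test locations (7 symmetric pairs); the full factorial with
    # 15 repetitions and 3 reliabilities gives the reference 1680-trial total
    exp1_vis_locations = c(-20, -10, -5, -2.5, -1.25, -0.65, -0.32,
                           0.32, 0.65, 1.25, 2.5, 5, 10, 20),
    exp1_deltas = c(-6, 0, 6),
    exp1_mean_locations = function(delta) {
      if (delta > 0) seq(-12, 6, by = 3)
      else if (delta < 0) seq(-6, 12, by = 3)
      else c(-9, -6, -3, 0, 3, 6, 9)
    },
    exp1_reps = 15L,
    # implicit (exp2) and explicit (exp3) spatial causal-inference experiments
    speaker_locations = c(-9, -6, -3, 0, 3, 6, 9),
    spatial_deltas = c(-24, -12, -6, -3, 0, 3, 6, 12, 24),
    exp2_reps = 8L,
    exp3_reps = 7L,
    # synchrony-judgment experiment (exp4), disparities in ms
    temporal_deltas = sort(c(0, outer(c(10, 20, 50, 80, 100, 150, 200,
                                        250, 300, 500, 700), c(-1, 1)))),
    exp4_reps = 25L,
    # heading / object-motion experiment (exp5): schedule only
    exp5_headings = c(0, -5, 5, -10, 10, -15, 15, -20, 20, -25, 25, -45, 45),
    exp5_speeds = c(0.07, 0.13, 0.8, 2.67, 5.33),
    exp5_directions = c(-1, 1),
    exp5_reps = 7L
  )
}
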