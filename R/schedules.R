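#' Trial schedules of the five behavioral experiments
#'
#' Each generator enumerates the full factorial design of one experiment and
#' returns it in a seeded random interleaved order. Columns follow one fixed
#' schema shared by all experiments (see [av_conventions()] for sign
#' conventions):
#'
#' * `experiment`: `exp1` ... `exp5`
#' * `condition`: `auditory_only`, `visual_only`, or `audio_visual`
#' * `eps_a`, `eps_v`: true cue locations in degrees (`NA` when the modality
#'   is absent); for exp5, `eps_v` carries the heading angle
#' * `reliability`: visual reliability level (`NA` for auditory-only trials)
#' * `delta`: signed disparity, `eps_a - eps_v` in degrees for spatial
#'   experiments, milliseconds (positive = visual leads) for exp4; for exp5 it
#'   carries the signed object speed (direction x speed, m/s)
#' * `repetition`: 1-based repetition index within the design cell
#'
#' Designs:
#' * `exp1` (unisensory + fusion): 105 auditory-only + 630 visual-only +
#'   945 combined trials = 1680; combined cues straddle the mean location at
#'   `mean +/- delta/2` with disparities 0, +/-6 degrees.
#' * `exp2` (implicit causal inference): 9 disparities x 7 speakers x
#'   3 reliabilities x 8 repetitions = 1512.
#' * `exp3` (explicit common-cause report): same factorial, 7 repetitions =
#'   1323.
#' * `exp4` (synchrony judgment): 23 temporal disparities x 25 = 575.
#' * `exp5` (heading / object motion, schedule only): 2 directions x
#'   5 speeds x 13 headings x 7 = 910.
#'
#' @param seed Integer seed controlling only the interleaving order.
#' @return A `data.frame` (one row per trial) with the schema above, carrying
#'   attribute `seed`.
#' @examples
#' nrow(make_schedule_exp1(1))  # 1680
#' @export
make_schedule_exp1 <- function(seed = 0L) {
  cv <- av_conventions()
  aud <- expand.grid(eps_a = cv$exp1_aud_locations,
                     repetition = seq_len(cv$exp1_reps))
  aud <- data.frame(condition = "auditory_only", eps_a = aud$eps_a,
                    eps_v = NA_real_, reliability = NA_character_,
                    delta = NA_real_, repetition = aud$repetition)
  vis <- expand.grid(eps_v = cv$exp1_vis_locations,
                     reliability = cv$reliabilities,
                     repetition = seq_len(cv$exp1_reps),
                     stringsAsFactors = FALSE)
  vis <- data.frame(condition = "visual_only", eps_a = NA_real_,
                    eps_v = vis$eps_v, reliability = vis$reliability,
                    delta = NA_real_, repetition = vis$repetition)
  comb <- do.call(rbind, lapply(cv$exp1_deltas, function(d) {
    g <- expand.grid(mean_loc = cv$exp1_mean_locations(d),
                     reliability = cv$reliabilities,
                     repetition = seq_len(cv$exp1_reps),
                     stringsAsFactors = FALSE)
    data.frame(condition = "audio_visual", eps_a = g$mean_loc + d / 2,
               eps_v = g$mean_loc - d / 2, reliability = g$reliability,
               delta = d, repetition = g$repetition)
  }))
  finish_schedule(rbind(aud, vis, comb), "exp1", seed)
}

#' @rdname make_schedule_exp1
#' @export
make_schedule_exp2 <- function(seed = 0L) {
  finish_schedule(spatial_ci_design(av_conventions()$exp2_reps), "exp2", seed)
}

#' @rdname make_schedule_exp1
#' @export
make_schedule_exp3 <- function(seed = 0L) {
  finish_schedule(spatial_ci_design(av_conventions()$exp3_reps), "exp3", seed)
}

#' @rdname make_schedule_exp1
#' @export
make_schedule_exp4 <- function(seed = 0L) {
  cv <- av_conventions()
  g <- expand.grid(delta = cv$temporal_deltas,
                   repetition = seq_len(cv$exp4_reps))
  d <- data.frame(condition = "audio_visual", eps_a = 0, eps_v = 0,
                  reliability = "high", delta = g$delta,
                  repetition = g$repetition)
  finish_schedule(d, "exp4", seed)
}

#' @rdname make_schedule_exp1
#' @export
make_schedule_exp5 <- function(seed = 0L) {
  cv <- av_conventions()
  g <- expand.grid(heading = cv$exp5_headings, speed = cv$exp5_speeds,
                   direction = cv$exp5_directions,
                   repetition = seq_len(cv$exp5_reps))
  d <- data.frame(condition = "visual_only", eps_a = NA_real_,
                  eps_v = g$heading, reliability = "high",
                  delta = g$direction * g$speed, repetition = g$repetition)
  finish_schedule(d, "exp5", seed)
}

# shared factorial of the implicit/explicit spatial causal-inference tasks:
# auditory cue on the speaker, visual cue at speaker - delta
spatial_ci_design <- function(reps) {
  cv <- av_conventions()
  g <- expand.grid(delta = cv$spatial_deltas,
                   eps_a = cv$speaker_locations,
                   reliability = cv$reliabilities,
                   repetition = seq_len(reps),
                   stringsAsFactors = FALSE)
  data.frame(condition = "audio_visual", eps_a = g$eps_a,
             eps_v = g$eps_a - g$delta, reliability = g$reliability,
             delta = g$delta, repetition = g$repetition)
}

finish_schedule <- function(d, experiment, seed) {
  d <- cbind(experiment = experiment, d)
  ord <- with_seed(seed, sample.int(nrow(d)))
  d <- d[ord, , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "seed") <- as.integer(seed)
  d
}

#' Write or read trial/response tables as CSV
#'
#' The on-disk schema has columns `experiment, condition, eps_a, eps_v,
#' reliability, delta, repetition, response, subject_id, group`; missing
#' values are written as empty fields. A bare schedule (no responses) is
#' written with an empty `response` column.
#'
#' @param data A schedule or response `data.frame`.
#' @param path CSV file path.
#' @return `read_response_csv()` returns the `data.frame`;
#'   `write_response_csv()` returns `path` invisibly.
#' @export
write_response_csv <- function(data, path) {
  cols <- c("experiment", "condition", "eps_a", "eps_v", "reliability",
            "delta", "repetition", "response", "subject_id", "group")
  for (cl in setdiff(cols, names(data))) data[[cl]] <- NA
  utils::write.csv(data[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_response_csv
#' @export
read_response_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  d$reliability <- as.character(d$reliability)
  d
}
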