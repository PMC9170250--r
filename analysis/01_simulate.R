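#!/usr/bin/env Rscript
# Step 1: simulate the study's synthetic cohorts.
#
# Builds a neurotypical-like control group and an ASD-like group (elevated
# common-cause prior, lowered explicit mixture weight, flatter/wider
# synchrony curve) and simulates all four audio-visual experiments per
# subject, plus the heading/object-motion trial schedule (no observer
# model). Writes one CSV per experiment and the generating parameters as
# JSON under results/data/.

suppressPackageStartupMessages(library(avci))

seed <- 20260921L
n_per_group <- 6L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spec <- cohort_spec()
cohort_spec_to_json(spec, file.path(out_dir, "cohort_spec.json"))

cohort <- make_cohort(n_per_group, n_per_group, spec, seed = seed,
                      experiments = c("exp1", "exp2", "exp3", "exp4"))

all_trials <- pool_cohort(cohort)
for (ex in unique(all_trials$experiment)) {
  path <- file.path(out_dir, paste0(ex, ".csv"))
  write_response_csv(all_trials[all_trials$experiment == ex, ], path)
  message(sprintf("%s: %d trials, %d subjects", path,
                  sum(all_trials$experiment == ex),
                  length(unique(all_trials$subject_id))))
}

# schedule-only heading/object-motion design
write_response_csv(make_schedule_exp5(seed), file.path(out_dir, "exp5.csv"))

# true generating parameters, for the recovery comparison in step 3
for (s in cohort) {
  params_to_json(s$params,
                 file.path(out_dir, paste0("params_", s$subject_id,
                                           ".json")))
}

truth <- data.frame(
  subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
  group = vapply(cohort, `[[`, character(1), "group"),
  p_common = vapply(cohort, function(s) s$params$p_common, numeric(1)),
  p_combined = vapply(cohort, function(s) s$params$p_combined, numeric(1)),
  sigma_a = vapply(cohort, function(s) s$params$sigma_a, numeric(1)))
write.csv(truth, file.path(out_dir, "true_parameters.csv"),
          row.names = FALSE)
message("cohort simulated: seed ", seed, ", ", 2 * n_per_group,
        " subjects")
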