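#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a baseline pressure recording with its
# ECG surrogate and landmark ground truth, an artifact-bearing recording, a
# two-group cohort of per-animal traces, vessel-ring images, and per-animal
# vasopressor dose-response tables. Everything downstream reads from
# results/simulated/.

suppressPackageStartupMessages(library(pulsewave))

seed <- 20260921
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## baseline recording: 60 beats at 2 kHz, 0.5 mmHg catheter noise
params <- beat_shape_params()
base <- generate_trace(params, 60, noise_sd = 0.5, seed = seed)
ecg <- generate_ecg(base$truth)
write_trace(base$trace, file.path(out, "baseline_trace.csv"))
write_results_json(base$truth$beats, file.path(out, "baseline_truth.json"))
message(sprintf("baseline: %d beats, %.1f s at %g Hz",
                nrow(base$truth$beats),
                length(base$trace$pressure) / base$trace$fs, base$trace$fs))

## recording with respiratory-swing artifact beats (+30% SBP)
art <- generate_trace(params, 60, noise_sd = 0.5,
                      artifact = list(n = 5, sbp_scale = 1.3),
                      seed = seed + 1)
write_trace(art$trace, file.path(out, "artifact_trace.csv"))
write_results_json(art$truth$beats, file.path(out, "artifact_truth.json"))
message(sprintf("artifact recording: beats %s perturbed",
                paste(which(art$truth$beats$artifact), collapse = ", ")))

## cohort: control vs stiffened/hypertensive contrast, n = 10 per group
cohort <- generate_cohort(n_per_group = 10, n_beats = 20, seed = seed + 2)
saveRDS_free <- function(df, path) # plain-text persistence only
  utils::write.csv(df, path, row.names = FALSE)
saveRDS_free(cohort, file.path(out, "cohort_truth.csv"))
traces <- attr(cohort, "traces")
for (i in seq_along(traces))
  write_trace(traces[[i]]$trace,
              file.path(out, sprintf("cohort_%s_%02d.csv",
                                     cohort$group[i], cohort$animal[i])))
message(sprintf("cohort: %d traces written", length(traces)))

## vessel rings: 3 sections per animal, thickness contrast ~space of +21%
ring_dir <- file.path(out, "rings")
dir.create(ring_dir, showWarnings = FALSE)
set.seed(seed + 3)
for (grp in c("control", "case")) {
  outer <- if (grp == "control") 56 else 59.4 # ~+21% wall thickness
  inner <- if (grp == "control") 40 else 40
  for (sec in 1:3) {
    ri <- generate_ring_image(
      ring_image_params(inner_radius = inner, outer_radius = outer,
                        noise_sd = 0.02,
                        branch_angles = if (sec == 2) c(45, 6) else NULL),
      seed = seed + 10 * sec + (grp == "case"))
    write_ring_image(ri$image,
                     file.path(ring_dir, sprintf("%s_sec%d.png", grp, sec)))
  }
}
message("rings: 2 groups x 3 sections written")

## dose-response tables: phenylephrine-like pressor responses per animal
dr_rows <- list()
set.seed(seed + 4)
for (grp in c("control", "case")) {
  emax <- if (grp == "control") 165 else 184
  for (a in 1:10) {
    tru <- four_pl_truth(bottom = 100, emax = emax + rnorm(1, 0, 3),
                         ed50 = 34 * exp(rnorm(1, 0, 0.15)), hill = 1.5,
                         doses = half_log_doses(1, 8), noise_sd = 2)
    d <- simulate_dose_response(tru, seed = seed + 100 + a)
    dr_rows[[length(dr_rows) + 1]] <-
      data.frame(dose_ug_per_kg = d$dose, response_mmHg = d$response,
                 animal_id = sprintf("%s_%02d", grp, a), agent = "pe",
                 group = grp)
  }
}
utils::write.csv(do.call(rbind, dr_rows),
                 file.path(out, "dose_response.csv"), row.names = FALSE)
message("dose-response: 20 animals x 8 half-log doses written")
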