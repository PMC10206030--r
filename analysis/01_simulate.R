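#!/usr/bin/env Rscript
# Generate the synthetic study cohorts: healthy and stroke subjects performing
# reaching tasks with no compensation (NC) or one of three compensation types
# (LF lean-forward, TR trunk rotation, SE shoulder elevation), recorded as
# 6-channel trunk-muscle NIRS at 16 Hz. Writes one CSV per trial plus a
# manifest per cohort under scratch/data/.

library(nirscomp)

seed <- 20260924L
counts <- c(NC = 10, LF = 20, TR = 20, SE = 20)  # per subject, study protocol
cfg <- sim_config()

for (grp in c("healthy", "stroke")) {
  n_subjects <- if (grp == "healthy") 4 else 3  # demonstration-scale cohorts
  ds <- generate_dataset(cfg, n_subjects = n_subjects, trials_per_class = counts,
                         seed = seed + (grp == "stroke"), group = grp)
  dir <- file.path("scratch", "data", grp)
  write_dataset(ds, dir)
  report <- validate_dataset(dir)
  cat(sprintf("%s cohort: %d subjects, %d trials (%s), validation %s\n",
              grp, n_subjects, report$n_trials,
              paste(names(report$classes), report$classes, sep = "=",
                    collapse = ", "),
              if (report$ok) "passed" else "FAILED"))
}

tr <- generate_trial(cfg, "LF", seed = seed)
cat(sprintf("example LF trial: %d samples/channel at %g Hz, %.1f%% dropped samples\n",
            length(tr$recording$series$ROEA$Hb), cfg$sampling_rate,
            100 * mean(unlist(tr$recording$missing_mask))))
cat("ground truth per channel: clean CMS/DMS series and activation intervals\n")
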