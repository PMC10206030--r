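#!/usr/bin/env Rscript
# Extract sliding-window time-domain features (MEA and STD per channel per
# component, 500 ms windows with 250 ms stride) from the active segments of
# each trial, for every signal type compared in the study. Writes one feature
# CSV per signal type per cohort under scratch/features/.

library(nirscomp)

dir.create(file.path("scratch", "features"), showWarnings = FALSE,
           recursive = TRUE)
signal_types <- c("RAW", "CBSI", "DBSI", "TFS", "CMS", "DMS")

for (grp in c("healthy", "stroke")) {
  trials <- read_dataset(file.path("scratch", "preprocessed", grp))
  for (m in signal_types) {
    feats <- pipeline_features(trials, method = m, preprocess = NULL)
    path <- file.path("scratch", "features",
                      sprintf("%s_%s.csv", grp, tolower(m)))
    write.csv(feats, path, row.names = FALSE)
    cat(sprintf("%s / %-4s: %5d windows x %2d features -> %s\n", grp, m,
                nrow(feats), length(feature_columns(feats)), path))
  }
}
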