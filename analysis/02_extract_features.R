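#!/usr/bin/env Rscript

# Stage 2: read the simulated cohort back from disk and run the full
# per-trial feature extraction: trimming, the two frame filters, chunk
# splitting, step detection, walking straightness, the 24 body-part
# angles, and aggregation by straightness group.
#
# Inputs:  scratch/cohort/ (from 01_simulate_cohort.R)
# Outputs: results/features.csv, results/arm_swing.csv, results/qc.csv

suppressPackageStartupMessages(library(gaitmood))

in_dir <- "scratch/cohort"
if (!dir.exists(in_dir)) {
  stop("run analysis/01_simulate_cohort.R first (no ", in_dir, ")")
}
dir.create("results", showWarnings = FALSE)

meta <- read_trial_metadata(file.path(in_dir, "metadata.csv"))
params <- feature_params()

feats <- list(); qc <- list()
for (k in seq_len(nrow(meta))) {
  tid <- meta$trial_id[k]
  s <- read_marker_table(file.path(in_dir, paste0(tid, ".csv")),
                         trial_id = tid)
  res <- suppressWarnings(extract_trial_features(s, params))
  feats[[k]] <- res$features
  row <- res$qc; row$direction <- res$direction
  qc[[k]] <- as.data.frame(row)
  message(sprintf(
    "  %s: %d usable straightness frames, %d steps, direction %s, %d feature rows",
    tid, row$n_frames_straightness, row$n_steps, res$direction,
    nrow(res$features)))
}
features <- do.call(rbind, feats)
qc <- do.call(rbind, qc)
arm_swing <- build_arm_swing_table(features, meta)

data.table::fwrite(features, "results/features.csv")
data.table::fwrite(arm_swing, "results/arm_swing.csv")
data.table::fwrite(qc, "results/qc.csv")
message(sprintf(
  "wrote %d feature rows and %d arm-swing rows for %d trials to results/",
  nrow(features), nrow(arm_swing), nrow(meta)))
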