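#!/usr/bin/env Rscript

# Stage 1: simulate a demonstration walking cohort and write it to disk in
# the same wide-CSV marker format a motion-capture export would use.
#
# The demo cohort is deliberately small (4 subjects x 3 stimuli, 150 s
# trials) so the file-based workflow stays quick; the full-scale study
# emulation (49 subjects) is exercised by scripts/acceptance.R, which runs
# the pipeline in memory instead of through files.
#
# Outputs: scratch/cohort/<trial>.csv, scratch/cohort/metadata.csv

suppressPackageStartupMessages(library(gaitmood))

out_dir <- "scratch/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(n_subjects = 4, trial_duration = 150,
                     corrupt_one = FALSE, seed = 7)
co <- generate_cohort(cfg)

message(sprintf("simulated %d trials from %d subjects", nrow(co$meta),
                cfg$n_subjects))
message("reported emotions: ",
        paste(names(table(co$meta$reported_emotion)),
              table(co$meta$reported_emotion), collapse = ", "))

for (k in seq_len(nrow(co$meta))) {
  s <- generate_trial(co$walks[[k]], co$meta[k, , drop = FALSE],
                      trim_guard_s = 60)
  path <- file.path(out_dir, paste0(co$meta$trial_id[k], ".csv"))
  write_marker_table(s, path)
  message(sprintf("  %s: %d frames, %s %s path (r = %.1f m) -> %s",
                  co$meta$trial_id[k], n_frames(s),
                  co$walks[[k]]$direction, co$walks[[k]]$path_kind,
                  co$walks[[k]]$radius, path))
}
write_trial_metadata(co$meta, file.path(out_dir, "metadata.csv"))
message("cohort written to ", out_dir)
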