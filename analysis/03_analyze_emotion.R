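#!/usr/bin/env Rscript

# Stage 3: the emotion-effect statistics on the extracted features:
#   - one-way ANOVA of every (angle, statistic, straightness group) on
#     reported and on expected emotion, with Tukey HSD follow-up for the
#     significant dependents
#   - multi-factor ANOVA of arm-swing magnitude on emotion, curvature,
#     arm side and gender (Type II SS)
#   - per-emotion, per-arm linear regression of arm swing on curvature
#
# Inputs:  results/features.csv, results/arm_swing.csv, scratch/cohort/
# Outputs: results/anova_oneway.csv, results/tukey.csv,
#          results/anova_multifactor.csv, results/regression.csv,
#          results/report.json

suppressPackageStartupMessages(library(gaitmood))

features <- as.data.frame(data.table::fread("results/features.csv"))
arm_swing <- as.data.frame(data.table::fread("results/arm_swing.csv"))
meta <- read_trial_metadata("scratch/cohort/metadata.csv")

oneway <- list(
  reported = one_way_anova(features, meta, "reported_emotion"),
  expected = one_way_anova(features, meta, "expected_emotion")
)
tukey <- list(
  reported = tukey_screen(oneway$reported, features, meta),
  expected = tukey_screen(oneway$expected, features, meta)
)
multifactor <- tryCatch(multi_factor_anova(arm_swing),
                        error = function(e) {
                          message("multi-factor ANOVA skipped: ",
                                  conditionMessage(e))
                          NULL
                        })
regression <- suppressWarnings(fit_curvature_regression(arm_swing))

n_sig <- sum(oneway$reported$p < 0.05, na.rm = TRUE)
message(sprintf(
  "one-way ANOVA (reported emotion): %d of %d dependents significant at 0.05",
  n_sig, nrow(oneway$reported)))
sig19 <- subset(oneway$reported, angle_index %in% c(19, 20) &
                  statistic == "sd" & p < 0.05)
message(sprintf(
  "  of these, %d are arm-swing magnitudes (angles 19/20, SD)",
  nrow(sig19)))
if (!is.null(multifactor)) {
  message("multi-factor ANOVA:")
  for (i in seq_len(nrow(multifactor))) {
    message(sprintf("  %-32s df=%2d F=%8.3f p=%.4g",
                    multifactor$term[i], multifactor$df[i],
                    multifactor$F[i], multifactor$p[i]))
  }
}
message("curvature regressions (swing = alpha + beta * curvature):")
for (i in seq_len(nrow(regression))) {
  message(sprintf("  %-8s %-5s alpha=%6.3f beta=%8.5f (n=%d)",
                  regression$emotion[i], regression$arm_side[i],
                  regression$alpha[i], regression$beta[i],
                  regression$n_obs[i]))
}

data.table::fwrite(rbind(oneway$reported, oneway$expected),
                   "results/anova_oneway.csv")
data.table::fwrite(rbind(tukey$reported, tukey$expected),
                   "results/tukey.csv")
if (!is.null(multifactor)) {
  data.table::fwrite(multifactor, "results/anova_multifactor.csv")
}
data.table::fwrite(regression, "results/regression.csv")
report <- build_report(oneway, tukey, multifactor, regression, arm_swing)
write_report(report, "results/report.json")
message("analysis tables written to results/")
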