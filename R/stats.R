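#' One-way ANOVA of angle features on an emotion factor
#'
#' For every (angle index, statistic, straightness group) combination the
#' trial-level values are tested for an emotion effect with a classical
#' between/within-groups F-test. The factor is either the stimulus label
#' (`expected_emotion`) or the self-report (`reported_emotion`).
#' Combinations with fewer than two factor levels carrying at least two
#' observations each are skipped. If all values are identical the test is
#' degenerate and F is reported as 0 with p = 1.
#'
#' No correction is applied across the many dependents by default (each
#' test is reported marginally, with Tukey adjusting only within a
#' dependent's level pairs); `adjust = "BH"` adds a Benjamini-Hochberg
#' adjusted column `p_adj` across all reported tests for users who want
#' family-wise discovery control.
#'
#' @param features Aggregated feature table (rows from
#'   [aggregate_features()] across trials).
#' @param meta Trial metadata.
#' @param factor_name `"reported_emotion"` or `"expected_emotion"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data.frame: `angle_index, statistic, straightness_group,
#'   factor_name, df_between, df_within, F, p, n_obs` (plus `p_adj` when
#'   `adjust = "BH"`).
#' @export
one_way_anova <- function(features, meta,
                          factor_name = c("reported_emotion",
                                          "expected_emotion"),
                          adjust = c("none", "BH")) {
  factor_name <- match.arg(factor_name)
  adjust <- match.arg(adjust)
  fac_all <- meta[[factor_name]][match(features$trial_id, meta$trial_id)]
  long <- rbind(
    data.frame(features[c("angle_index", "straightness_group")],
               statistic = "mean", value = features$mean_deg,
               fac = fac_all, stringsAsFactors = FALSE),
    data.frame(features[c("angle_index", "straightness_group")],
               statistic = "sd", value = features$sd_deg,
               fac = fac_all, stringsAsFactors = FALSE)
  )
  out <- list()
  for (key in split(long, long[c("angle_index", "statistic",
                                 "straightness_group")], drop = TRUE)) {
    tab <- table(key$fac)
    usable <- names(tab)[tab >= 2]
    if (length(usable) < 2) next
    d <- key[key$fac %in% usable, , drop = FALSE]
    res <- .anova_f(d$value, factor(d$fac))
    out[[length(out) + 1L]] <- data.frame(
      angle_index = key$angle_index[1], statistic = key$statistic[1],
      straightness_group = key$straightness_group[1],
      factor_name = factor_name,
      df_between = res$df1, df_within = res$df2,
      F = res$F, p = res$p, n_obs = nrow(d), stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(angle_index = integer(0), statistic = character(0),
                      straightness_group = character(0),
                      factor_name = character(0), df_between = integer(0),
                      df_within = integer(0), F = numeric(0),
                      p = numeric(0), n_obs = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$statistic,
                   match(res$straightness_group,
                         straightness_groups()$label),
                   res$angle_index), , drop = FALSE]
  if (adjust == "BH") res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res
}

# Between/within F for a one-way layout, with the degenerate
# zero-variance-equal-means case reported as F = 0.
.anova_f <- function(values, fac) {
  fit <- stats::aov(values ~ fac)
  tab <- summary(fit)[[1]]
  F <- tab[1, "F value"]
  p <- tab[1, "Pr(>F)"]
  if (!is.finite(F)) {
    if (stats::var(values) < .Machine$double.eps) {
      F <- 0; p <- 1
    } else {
      # zero within-group variance but distinct means: infinite evidence
      p <- 0
    }
  }
  list(F = F, p = p, df1 = tab[1, "Df"], df2 = tab[2, "Df"], fit = fit)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range-adjusted p-values for all unordered pairs of factor
#' levels, as the follow-up to a significant one-way ANOVA screen. Levels
#' with fewer than two observations are dropped (their pairs are skipped).
#'
#' @param values Numeric observations.
#' @param levels_fac Factor (or character) of the same length.
#' @return A data.frame `level_a, level_b, diff, p_adj`.
#' @export
tukey_hsd <- function(values, levels_fac) {
  fac <- factor(levels_fac)
  tab <- table(fac)
  keep <- names(tab)[tab >= 2]
  if (length(keep) < 2) {
    return(data.frame(level_a = character(0), level_b = character(0),
                      diff = numeric(0), p_adj = numeric(0)))
  }
  sel <- fac %in% keep
  fac <- droplevels(fac[sel])
  fit <- stats::aov(values[sel] ~ fac)
  tk <- stats::TukeyHSD(fit)$fac
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(level_a = vapply(pairs, `[`, character(1), 1),
             level_b = vapply(pairs, `[`, character(1), 2),
             diff = tk[, "diff"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screened Tukey follow-up over a one-way ANOVA result table
#'
#' Runs [tukey_hsd()] for every dependent whose one-way ANOVA p-value
#' passed the screening threshold, mirroring the report-only-significant
#' convention.
#'
#' @param anova_tab Result of [one_way_anova()].
#' @param features,meta As in [one_way_anova()].
#' @param alpha Screening threshold (default 0.05).
#' @return A data.frame of Tukey rows with the dependent's identifiers
#'   attached.
#' @export
tukey_screen <- function(anova_tab, features, meta, alpha = 0.05) {
  hits <- anova_tab[is.finite(anova_tab$p) & anova_tab$p < alpha, ,
                    drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    rows <- features[features$angle_index == h$angle_index &
                       features$straightness_group == h$straightness_group, ,
                     drop = FALSE]
    vals <- if (h$statistic == "mean") rows$mean_deg else rows$sd_deg
    fac <- meta[[h$factor_name]][match(rows$trial_id, meta$trial_id)]
    tk <- tukey_hsd(vals, fac)
    if (nrow(tk) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      angle_index = h$angle_index, statistic = h$statistic,
      straightness_group = h$straightness_group,
      factor_name = h$factor_name, tk, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(angle_index = integer(0), statistic = character(0),
                      straightness_group = character(0),
                      factor_name = character(0), level_a = character(0),
                      level_b = character(0), diff = numeric(0),
                      p_adj = numeric(0)))
  }
  do.call(rbind, out)
}

#' Multi-factor ANOVA of arm-swing magnitude
#'
#' Linear-model F-tests of arm-swing magnitude on four main effects —
#' reported emotion (3 levels), signed curvature treated as a 7-level
#' categorical factor, arm side (2) and gender (2) — plus the four
#' interactions emotion:curvature, emotion:side, curvature:side and
#' emotion:gender. Sums of squares are Type II by default (the design is
#' unbalanced); Type III is available via `ss_type`.
#'
#' @param arm_swing Arm-swing table from [build_arm_swing_table()].
#' @param ss_type 2 or 3.
#' @return A data.frame `term, df, F, p`.
#' @export
multi_factor_anova <- function(arm_swing, ss_type = 2) {
  d <- data.frame(
    y = arm_swing$swing_sd_deg,
    emotion = factor(arm_swing$reported_emotion),
    curvature = factor(arm_swing$curvature,
                       levels = sort(unique(arm_swing$curvature))),
    side = factor(arm_swing$arm_side),
    gender = factor(arm_swing$gender)
  )
  for (v in c("emotion", "curvature", "side", "gender")) {
    if (nlevels(d[[v]]) < 2) {
      stop("factor '", v, "' has fewer than 2 levels in the arm-swing table",
           call. = FALSE)
    }
  }
  if (ss_type == 3) {
    op <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(op))
  }
  fit <- stats::lm(y ~ emotion + curvature + side + gender +
                     emotion:curvature + emotion:side + curvature:side +
                     emotion:gender, data = d)
  a <- car::Anova(fit, type = ss_type, singular.ok = TRUE)
  tab <- as.data.frame(a)
  terms <- rownames(tab)
  keep <- !terms %in% c("Residuals", "(Intercept)")
  rename <- c(emotion = "reported_emotion", curvature = "curvature",
              side = "angle_side", gender = "gender",
              "emotion:curvature" = "reported_emotion:curvature",
              "emotion:side" = "reported_emotion:angle_side",
              "curvature:side" = "curvature:angle_side",
              "emotion:gender" = "reported_emotion:gender")
  out <- data.frame(
    term = unname(ifelse(terms[keep] %in% names(rename),
                         rename[terms[keep]], terms[keep])),
    df = tab$Df[keep],
    F = tab$`F value`[keep],
    p = tab$`Pr(>F)`[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "residual_df") <- tab$Df[terms == "Residuals"]
  out
}

#' Per-emotion, per-arm linear regression of arm swing on curvature
#'
#' Ordinary least squares of the arm-swing magnitude on the signed
#' curvature value within each of the six (emotion, arm side) strata:
#' `swing = alpha + beta * curvature`. Strata with fewer than two distinct
#' curvature values are omitted with a warning.
#'
#' @param arm_swing Arm-swing table from [build_arm_swing_table()].
#' @return A data.frame `emotion, arm_side, alpha, beta, n_obs`.
#' @export
fit_curvature_regression <- function(arm_swing) {
  out <- list()
  for (emo in c("Happy", "Neither", "Sad")) {
    for (side in c("left", "right")) {
      d <- arm_swing[arm_swing$reported_emotion == emo &
                       arm_swing$arm_side == side, , drop = FALSE]
      if (nrow(d) == 0) next
      if (nrow(d) < 2 || length(unique(d$curvature)) < 2) {
        warning("regression stratum (", emo, ", ", side,
                ") is degenerate; omitted", call. = FALSE)
        next
      }
      fit <- stats::lm(swing_sd_deg ~ curvature, data = d)
      out[[length(out) + 1L]] <- data.frame(
        emotion = emo, arm_side = side,
        alpha = unname(stats::coef(fit)[1]),
        beta = unname(stats::coef(fit)[2]),
        n_obs = nrow(d), stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(emotion = character(0), arm_side = character(0),
                      alpha = numeric(0), beta = numeric(0),
                      n_obs = integer(0)))
  }
  do.call(rbind, out)
}

#' Assemble the machine-readable analysis report
#'
#' Collects the one-way ANOVA tables, their Tukey follow-ups, the
#' multi-factor ANOVA, the emotion/gender Tukey comparisons on the pooled
#' arm-swing data, and the six curvature regressions into one list
#' mirroring the result-table layout of the analysis, with significant
#' entries flagged at `alpha`.
#'
#' @param oneway List of [one_way_anova()] tables (by factor).
#' @param tukey List of [tukey_screen()] tables (by factor).
#' @param multifactor [multi_factor_anova()] table.
#' @param regression [fit_curvature_regression()] table.
#' @param arm_swing The arm-swing table (for the pooled emotion/gender
#'   Tukey tests).
#' @param alpha Significance level (default 0.05).
#' @return A list ready for [write_report()].
#' @export
build_report <- function(oneway = list(), tukey = list(),
                         multifactor = NULL, regression = NULL,
                         arm_swing = NULL, alpha = 0.05) {
  rep <- list(schema = "gaitmood-report-1", alpha = alpha)
  rep$oneway <- lapply(oneway, function(t) {
    if (!is.null(t) && nrow(t) > 0) t$significant <- t$p < alpha
    t
  })
  rep$tukey <- tukey
  if (!is.null(multifactor) && nrow(multifactor) > 0) {
    multifactor$significant <- multifactor$p < alpha
  }
  rep$multifactor <- multifactor
  if (!is.null(arm_swing) && nrow(arm_swing) > 0) {
    rep$emotion_pairs <- tukey_hsd(arm_swing$swing_sd_deg,
                                   arm_swing$reported_emotion)
    rep$gender_pairs <- tukey_hsd(arm_swing$swing_sd_deg,
                                  arm_swing$gender)
  }
  rep$regression <- regression
  rep
}

#' Write an analysis report to JSON
#'
#' @param report List from [build_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
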