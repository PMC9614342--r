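# Minimal feature table: one angle/statistic/group cell across trials.
feature_rows <- function(values, trial_ids, angle = 19L,
                         group = "-5 to 5") {
  data.frame(trial_id = trial_ids, straightness_group = group,
             angle_index = angle, mean_deg = values, sd_deg = values,
             n_frames = 1000L, stringsAsFactors = FALSE)
}

meta_for <- function(trial_ids, emotions) {
  expected <- c(Happy = "Positive", Sad = "Negative", Neither = "Neutral")
  trial_metadata(trial_ids, paste0("s", seq_along(trial_ids)),
                 unname(expected[emotions]), emotions,
                 rep("Male", length(trial_ids)))
}

test_that("one-way ANOVA: identical groups give F = 0", {
  ids <- sprintf("t%02d", 1:9)
  # every emotion level observes the same triplet {1, 2, 3}
  feats <- feature_rows(rep(c(1, 2, 3), 3), ids)
  meta <- meta_for(ids, rep(c("Happy", "Sad", "Neither"), each = 3))
  res <- one_way_anova(feats, meta)
  expect_equal(res$F, rep(0, nrow(res)), tolerance = 1e-12)
  expect_equal(res$p, rep(1, nrow(res)), tolerance = 1e-12)
})

test_that("two-level one-way F equals the squared pooled t", {
  set.seed(21)
  x <- rnorm(12, 5); y <- rnorm(12, 6)
  ids <- sprintf("t%02d", 1:24)
  feats <- feature_rows(c(x, y), ids)
  meta <- meta_for(ids, rep(c("Happy", "Sad"), each = 12))
  res <- one_way_anova(feats, meta)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$F[res$statistic == "mean"], unname(tt$statistic^2),
               tolerance = 1e-10)
  expect_equal(res$p[res$statistic == "mean"], tt$p.value,
               tolerance = 1e-10)
  expect_equal(res$df_between, c(1L, 1L))
})

test_that("optional BH adjustment is monotone and bounded", {
  set.seed(77)
  ids <- sprintf("t%02d", 1:30)
  feats <- rbind(
    feature_rows(rnorm(30, 4, 0.5), ids, angle = 19L),
    feature_rows(rnorm(30, 9, 0.5), ids, angle = 20L)
  )
  meta <- meta_for(ids, rep(c("Happy", "Sad", "Neither"), each = 10))
  res <- one_way_anova(feats, meta, adjust = "BH")
  expect_true("p_adj" %in% names(res))
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p_adj <= 1))
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
})

test_that("ANOVA sum-of-squares identity holds", {
  set.seed(5)
  vals <- rnorm(30, 10, 2)
  fac <- rep(c("Happy", "Sad", "Neither"), each = 10)
  fit <- aov(vals ~ factor(fac))
  tab <- summary(fit)[[1]]
  total_ss <- sum((vals - mean(vals))^2)
  expect_equal(sum(tab[["Sum Sq"]]), total_ss, tolerance = 1e-8)
})

test_that("levels with too few observations are skipped", {
  ids <- sprintf("t%02d", 1:5)
  feats <- feature_rows(c(1, 2, 3, 4, 9), ids)
  meta <- meta_for(ids, c("Happy", "Happy", "Sad", "Sad", "Neither"))
  res <- one_way_anova(feats, meta)
  # Neither has a single observation: reduced to a two-level test
  expect_equal(unique(res$df_between), 1L)
  expect_equal(unique(res$n_obs), 4L)
})

test_that("Tukey HSD produces all pairs with sane adjusted p-values", {
  set.seed(8)
  a <- rnorm(20, 0)
  vals <- c(a, a, rnorm(20, 10))  # A and B identical, C far away
  fac <- rep(c("A", "B", "C"), each = 20)
  tk <- tukey_hsd(vals, fac)
  expect_equal(nrow(tk), 3)
  identical_pair <- tk[tk$level_a == "B" & tk$level_b == "A", ]
  expect_gt(identical_pair$p_adj, 0.99)
  separated <- tk[tk$level_a == "C", ]
  expect_true(all(separated$p_adj < 0.001))
  # a level with one observation is dropped
  tk2 <- tukey_hsd(c(vals, 5), c(fac, "D"))
  expect_equal(nrow(tk2), 3)
})

test_that("Tukey screening only follows up significant dependents", {
  set.seed(31)
  ids <- sprintf("t%02d", 1:30)
  emo <- rep(c("Happy", "Sad", "Neither"), each = 10)
  # strong effect on the sd statistic only
  feats <- data.frame(trial_id = ids, straightness_group = "-5 to 5",
                      angle_index = 19L,
                      mean_deg = rnorm(30, 10, 1),
                      sd_deg = c(rnorm(10, 2), rnorm(10, 12), rnorm(10, 22)),
                      n_frames = 1000L)
  meta <- meta_for(ids, emo)
  an <- one_way_anova(feats, meta)
  tk <- tukey_screen(an, feats, meta, alpha = 0.05)
  expect_true("sd" %in% tk$statistic)
  expect_equal(sum(tk$statistic == "sd"), 3)  # three emotion pairs
})

test_that("multi-factor ANOVA reports the expected degrees of freedom", {
  aw <- simulate_arm_swing_table(seed = 3)
  res <- multi_factor_anova(aw)
  df <- setNames(res$df, res$term)
  expect_equal(df[["reported_emotion"]], 2)
  expect_equal(df[["curvature"]], 6)
  expect_equal(df[["angle_side"]], 1)
  expect_equal(df[["gender"]], 1)
  expect_equal(df[["reported_emotion:curvature"]], 12)
  expect_equal(df[["reported_emotion:angle_side"]], 2)
  expect_equal(df[["curvature:angle_side"]], 6)
  expect_equal(df[["reported_emotion:gender"]], 2)
  # the emotion effect injected by the simulator is detected
  expect_lt(res$p[res$term == "reported_emotion"], 1e-6)
})

test_that("Type II and Type III agree on balanced designs", {
  # a fully crossed design with equal cell counts
  set.seed(12)
  g <- expand.grid(emotion = c("Happy", "Sad", "Neither"),
                   curvature = c(-30, -20, -10, 0, 10, 20, 30),
                   side = c("left", "right"),
                   gender = c("Male", "Female"),
                   rep = 1:2, stringsAsFactors = FALSE)
  aw <- data.frame(trial_id = sprintf("t%03d", seq_len(nrow(g))),
                   straightness_group = "-5 to 5",
                   curvature = g$curvature, arm_side = g$side,
                   swing_sd_deg = rnorm(nrow(g), 4, 0.5) +
                     0.5 * (g$emotion == "Happy"),
                   n_frames = 1000L,
                   reported_emotion = g$emotion,
                   expected_emotion = "Neutral", gender = g$gender)
  t2 <- multi_factor_anova(aw, ss_type = 2)
  t3 <- multi_factor_anova(aw, ss_type = 3)
  for (term in t2$term) {
    expect_equal(t2$F[t2$term == term], t3$F[t3$term == term],
                 tolerance = 1e-8)
  }
})

test_that("effects concentrate where they are injected", {
  # emotion shifts swing levels; side and gender carry no effect
  set.seed(44)
  aw <- simulate_arm_swing_table(
    n_per_emotion = c(Happy = 49, Sad = 49, Neither = 49), seed = 44)
  res <- multi_factor_anova(aw)
  expect_lt(res$p[res$term == "reported_emotion"], 0.001)
  expect_lt(res$p[res$term == "curvature"], 0.05)
  expect_gt(res$p[res$term == "angle_side"], 0.05)
  expect_gt(res$p[res$term == "gender"], 0.05)
})

test_that("curvature regression recovers exact and degenerate lines", {
  curv <- rep(c(-30, -20, -10, 0, 10, 20, 30), each = 2)
  aw <- data.frame(trial_id = "t", straightness_group = "-5 to 5",
                   curvature = curv, arm_side = rep(c("left", "right"), 7),
                   swing_sd_deg = 2 + 0.5 * curv, n_frames = 1000L,
                   reported_emotion = "Happy", expected_emotion = "Positive",
                   gender = "Male")
  fits <- suppressWarnings(fit_curvature_regression(aw))
  hl <- fits[fits$emotion == "Happy" & fits$arm_side == "left", ]
  expect_equal(hl$alpha, 2, tolerance = 1e-10)
  expect_equal(hl$beta, 0.5, tolerance = 1e-10)
  # constant swing: zero slope
  aw$swing_sd_deg <- 4
  fits2 <- suppressWarnings(fit_curvature_regression(aw))
  expect_equal(fits2$beta[fits2$emotion == "Happy"], c(0, 0),
               tolerance = 1e-10)
  # single curvature level: stratum omitted with warning
  aw3 <- aw[aw$curvature == 0 & aw$arm_side == "left", ]
  expect_warning(fits3 <- fit_curvature_regression(aw3), "degenerate")
  expect_equal(nrow(fits3[fits3$emotion == "Happy", ]), 0)
})

test_that("regression residuals are orthogonal to the design", {
  aw <- simulate_arm_swing_table(seed = 9)
  d <- aw[aw$reported_emotion == "Happy" & aw$arm_side == "left", ]
  fit <- lm(swing_sd_deg ~ curvature, data = d)
  expect_lt(abs(sum(residuals(fit))), 1e-8)
  expect_lt(abs(sum(residuals(fit) * d$curvature)), 1e-8)
})

test_that("reports are structured, flagged and serialisable", {
  aw <- simulate_arm_swing_table(
    n_per_emotion = c(Happy = 10, Sad = 10, Neither = 10), seed = 2)
  mf <- multi_factor_anova(aw)
  reg <- fit_curvature_regression(aw)
  rep <- build_report(multifactor = mf, regression = reg, arm_swing = aw)
  expect_equal(rep$schema, "gaitmood-report-1")
  expect_true(is.logical(rep$multifactor$significant))
  expect_equal(nrow(rep$emotion_pairs), 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$schema, "gaitmood-report-1")
  # deterministic bytes
  path2 <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path2)
  expect_identical(readLines(path), readLines(path2))
  # empty report still carries the schema header
  rep0 <- build_report()
  expect_equal(rep0$schema, "gaitmood-report-1")
})
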