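test_that("inter-foot distance is the top-view Euclidean distance", {
  xyz <- list(
    LeftAnkleOut = rbind(c(0, 0.1, 0), c(1, 5, 1), c(0, 0.0, 0)),
    RightAnkleOut = rbind(c(0.3, 0.2, 0.4), c(1, -5, 1), c(0, 9, 0))
  )
  s <- series_from_list(xyz)
  chunk <- list(trial_id = "manual", purpose = "straightness",
                frames = 0:2)
  d <- interfoot_distance(chunk, s)
  expect_equal(d, c(0.5, 0, 0))  # 3-4-5 triangle; coincident; Y ignored
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  x <- rep(2.5, 100)
  expect_equal(smooth_distance(x), x, tolerance = 1e-12)
  t <- seq_len(200)
  cubic <- 1 + 0.01 * t - 2e-4 * t^2 + 1e-6 * t^3
  expect_equal(smooth_distance(cubic, order = 3), cubic, tolerance = 1e-9)
  # noise variance shrinks
  set.seed(1)
  noisy <- sin(2 * pi * t / 60) + rnorm(200, 0, 0.2)
  expect_lt(var(diff(smooth_distance(noisy))), var(diff(noisy)))
  # too-short signal passes through with warning
  expect_warning(out <- smooth_distance(1:5), "shorter than")
  expect_equal(out, 1:5)
})

test_that("peak finder honours prominence and separation", {
  t <- seq(0, 10, by = 0.01)
  x <- sin(2 * pi * t)  # 10 peaks, unit prominence
  p <- find_peaks(x, min_distance = 50, min_prominence = 0.5)
  expect_length(p, 10)
  # a small ripple on a ramp makes many shallow local maxima whose
  # prominence stays far below the ripple's full amplitude
  x2 <- t + 0.02 * sin(20 * pi * t)
  expect_length(find_peaks(x2, min_prominence = 0.05), 0)
  expect_gt(length(find_peaks(x2, min_prominence = 0.001)), 50)
  # monotone signal: no peaks
  expect_length(find_peaks(seq_len(100)), 0)
})

test_that("step detection recovers the configured cadence", {
  w <- clean_walk(duration_s = 80, seed = 5)
  s <- generate_trial(w, clean_meta(), trim_guard_s = 0)
  tr <- trim_trial(s, 10)
  ch <- split_chunks(ankle_availability_mask(tr))[[1]]
  d <- smooth_distance(interfoot_distance(ch, tr))
  steps <- detect_steps(d, ch, tr)
  # 60 s at 1.8 steps/s
  expect_gt(nrow(steps), 0.95 * 60 * 1.8)
  expect_lt(nrow(steps), 1.05 * 60 * 1.8)
  # sides alternate on clean data
  expect_true(all(steps$side[-1] != steps$side[-nrow(steps)]))
  # frames strictly increasing
  expect_true(all(diff(steps$frame) > 0))
})

test_that("too few steps discard the chunk", {
  # monotone distance: no peaks at all
  xyz <- list(
    LeftAnkleOut = cbind(seq(0, 1, length.out = 100), 0.1, 0),
    RightAnkleOut = cbind(0, 0.1, 0)
  )
  s <- series_from_list(xyz)
  ch <- list(trial_id = "manual", purpose = "straightness", frames = 0:99)
  d <- interfoot_distance(ch, s)
  steps <- detect_steps(smooth_distance(d, 31, 3), ch, s)
  expect_equal(nrow(steps), 0)
})

test_that("straightness angles follow polygon closed forms", {
  # collinear steps: zero turning
  st <- data.frame(frame = c(0, 50, 100, 150),
                   side = c("left", "right", "left", "right"),
                   x = c(0, 1, 2, 3), z = c(0, 0.5, 1, 1.5))
  a <- straightness_angles(st)
  expect_equal(a$theta, c(0, 0), tolerance = 1e-12)

  # regular polygons: exterior angle 360/N, sign by traversal direction
  for (N in c(18, 36, 72)) {
    ccw <- straightness_angles(polygon_steps(N, dir = 1))
    expect_equal(ccw$theta, rep(360 / N, N - 1), tolerance = 1e-9)
    cw <- straightness_angles(polygon_steps(N, dir = -1))
    expect_equal(cw$theta, rep(-360 / N, N - 1), tolerance = 1e-9)
  }
})

test_that("zero-length step vectors are skipped with a warning", {
  st <- data.frame(frame = c(0, 50, 100),
                   side = c("left", "right", "left"),
                   x = c(0, 0, 1), z = c(0, 0, 0))
  expect_warning(a <- straightness_angles(st), "zero-length")
  expect_equal(nrow(a), 0)
})

test_that("straightness assignment averages overlapping triples", {
  ang <- data.frame(frame_start = c(0L, 10L), frame_mid = c(10L, 20L),
                    frame_end = c(20L, 30L), theta = c(10, 20))
  st <- assign_straightness(ang)
  # frames 0-9: first triple only; 10-19 shared by both triples; 20-30:
  # last triple only
  expect_equal(st$theta[st$frame == 5], 10)
  expect_equal(st$theta[st$frame == 15], 15)
  expect_equal(st$theta[st$frame == 25], 20)
  expect_equal(st$theta[st$frame == 30], 20)
  expect_false(31 %in% st$frame)
  # a single triple gives every covered frame the same value
  st1 <- assign_straightness(ang[1, ])
  expect_true(all(st1$theta == 10))
  expect_equal(range(st1$frame), c(0, 20))
})

test_that("straightness bins are half-open over [-35, 35)", {
  expect_equal(bin_straightness(0), "-5 to 5")
  expect_equal(bin_straightness(5), "5 to 15")
  expect_equal(bin_straightness(-5), "-5 to 5")
  expect_equal(bin_straightness(-5.001), "-15 to -5")
  expect_equal(bin_straightness(34.999), "25 to 35")
  expect_true(is.na(bin_straightness(35)))
  expect_true(is.na(bin_straightness(40)))
  expect_true(is.na(bin_straightness(-35.001)))
  expect_equal(bin_straightness(-35), "-35 to -25")
  g <- straightness_groups()
  expect_equal(nrow(g), 7)
  expect_equal(g$hi - g$lo, rep(10, 7))
})

test_that("body-part angles match hand geometry", {
  xyz <- list(
    A = rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0)),
    V = rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)),
    B = rbind(c(0, 1, 0), c(-1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  )
  # stand-in marker names so compute_angles can be reused
  names(xyz) <- c("LeftAnkleOut", "LeftKneeOut", "WaistLeftFront")
  s <- series_from_list(xyz)
  defs <- angle_definitions()[1, ]
  a <- compute_angles(s, 0:2, defs)
  expect_equal(as.vector(a), c(90, 180, 60), tolerance = 1e-9)
})

test_that("aggregation matches a brute-force recomputation", {
  set.seed(9)
  frames <- 0:199
  theta <- runif(200, -40, 40)
  straightness <- data.frame(frame = frames, theta = theta)
  ang <- matrix(runif(200 * 24, 0, 180), ncol = 24,
                dimnames = list(NULL, as.character(1:24)))
  ang[sample(length(ang), 500)] <- NA
  agg <- aggregate_features(straightness, ang, frames, "t")
  expect_true(all(agg$n_frames >= 2))
  expect_true(all(agg$mean_deg >= 0 & agg$mean_deg <= 180))
  expect_true(all(agg$sd_deg >= 0))
  for (i in sample(nrow(agg), 10)) {
    row <- agg[i, ]
    sel <- !is.na(bin_straightness(theta)) &
      bin_straightness(theta) == row$straightness_group &
      !is.na(ang[, as.character(row$angle_index)])
    vals <- ang[sel, as.character(row$angle_index)]
    expect_equal(row$mean_deg, mean(vals))
    expect_equal(row$sd_deg, sd(vals))
    expect_equal(row$n_frames, length(vals))
  }
  # a sinusoidal angle aggregates to SD ~ amplitude / sqrt(2)
  t <- seq(0, 100, by = 0.01)
  sine <- 90 + 7 * sin(2 * pi * t)
  st2 <- data.frame(frame = seq_along(t) - 1L, theta = 0)
  ang2 <- matrix(sine, ncol = 1, dimnames = list(NULL, "19"))
  agg2 <- aggregate_features(st2, ang2, st2$frame, "t")
  expect_equal(agg2$sd_deg, 7 / sqrt(2), tolerance = 1e-3)
})

test_that("curvature conversion covers all 14 group-side cells", {
  expect_equal(curvature_from_group("-35 to -25", "left"), 30L)
  expect_equal(curvature_from_group("-35 to -25", "right"), -30L)
  expect_equal(curvature_from_group("-25 to -15", "left"), 20L)
  expect_equal(curvature_from_group("-25 to -15", "right"), -20L)
  expect_equal(curvature_from_group("-15 to -5", "left"), 10L)
  expect_equal(curvature_from_group("-15 to -5", "right"), -10L)
  expect_equal(curvature_from_group("-5 to 5", "left"), 0L)
  expect_equal(curvature_from_group("-5 to 5", "right"), 0L)
  expect_equal(curvature_from_group("5 to 15", "left"), -10L)
  expect_equal(curvature_from_group("5 to 15", "right"), 10L)
  expect_equal(curvature_from_group("15 to 25", "left"), -20L)
  expect_equal(curvature_from_group("15 to 25", "right"), 20L)
  expect_equal(curvature_from_group("25 to 35", "left"), -30L)
  expect_equal(curvature_from_group("25 to 35", "right"), 30L)
  expect_error(curvature_from_group("0 to 10", "left"), "unknown")
})

test_that("arm swing table has one row per group and side", {
  feats <- data.frame(
    trial_id = "t", straightness_group = rep(straightness_groups()$label, 2),
    angle_index = rep(c(19L, 20L), each = 7),
    mean_deg = 18, sd_deg = 4, n_frames = 1000L
  )
  meta <- clean_meta("Happy", "t")
  aw <- build_arm_swing_table(feats, meta)
  expect_equal(nrow(aw), 14)
  expect_setequal(aw$arm_side, c("left", "right"))
  expect_equal(sort(unique(aw$curvature)), c(-30L, -20L, -10L, 0L, 10L,
                                             20L, 30L))
  expect_true(all(aw$reported_emotion == "Happy"))
  # missing group: no row; short row dropped by frame support
  feats2 <- feats[feats$straightness_group != "-5 to 5", ]
  feats2$n_frames[1] <- 10L
  aw2 <- build_arm_swing_table(feats2, meta)
  expect_equal(nrow(aw2), 11)
  expect_false("-5 to 5" %in% aw2$straightness_group)
})

test_that("walk direction classification separates CW, CCW and mixed", {
  expect_equal(classify_walk_direction(
    data.frame(frame = 1:100, theta = rep(12, 100))), "CCW")
  expect_equal(classify_walk_direction(
    data.frame(frame = 1:100, theta = rep(-12, 100))), "CW")
  expect_equal(classify_walk_direction(
    data.frame(frame = 1:100, theta = rep(c(-12, 12), 50))), "both")
  expect_warning(
    d <- classify_walk_direction(data.frame(frame = 1:10, theta = rep(0, 10))),
    "no curved frames")
  expect_equal(d, "both")
})

test_that("mirroring flips straightness and swaps arm roles", {
  w <- clean_walk(duration_s = 120, seed = 21)
  s <- generate_trial(w, clean_meta(), trim_guard_s = 30)
  p <- feature_params(trim_seconds = 30)
  res <- extract_trial_features(s, p)
  res_m <- extract_trial_features(mirror_x(s), p)

  expect_equal(res$direction, "CCW")
  expect_equal(res_m$direction, "CW")
  # per-frame straightness flips sign exactly
  common <- intersect(res$straightness$frame, res_m$straightness$frame)
  expect_gt(length(common), 1000)
  expect_equal(
    res_m$straightness$theta[match(common, res_m$straightness$frame)],
    -res$straightness$theta[match(common, res$straightness$frame)],
    tolerance = 1e-6)

  # the swing magnitude carries over to the mirrored group unchanged,
  # while the arm's inside/outside role (the curvature sign) flips
  g <- straightness_groups()
  flip_group <- function(lab) {
    i <- match(lab, g$label)
    g$label[8 - i]
  }
  meta <- clean_meta("Happy")
  aw <- build_arm_swing_table(res$features, meta)
  aw_m <- build_arm_swing_table(res_m$features, meta)
  key <- function(d, grp) paste(grp, d$arm_side)
  m <- match(key(aw, aw$straightness_group),
             key(aw_m, flip_group(aw_m$straightness_group)))
  expect_false(anyNA(m))
  expect_equal(aw$swing_sd_deg, aw_m$swing_sd_deg[m], tolerance = 1e-6)
  expect_equal(aw$curvature, -aw_m$curvature[m])
})

test_that("radius and straightness are inversely related on circles", {
  med <- numeric(3)
  radii <- c(midbin_radius(30), midbin_radius(20), midbin_radius(10))
  for (i in seq_along(radii)) {
    w <- clean_walk(radius = radii[i], duration_s = 120, seed = 33)
    s <- generate_trial(w, clean_meta(), trim_guard_s = 30)
    res <- extract_trial_features(s, feature_params(trim_seconds = 30))
    med[i] <- median(abs(res$straightness$theta))
  }
  expect_true(all(diff(med) < 0))
  expect_equal(med, c(30, 20, 10), tolerance = 0.05)
})
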