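#' Walking-trial configuration for the synthetic gait generator
#'
#' Describes one simulated walking trial: the path geometry, gait timing,
#' the emotion-dependent arm-swing law, and the corruption processes
#' (coordinate noise, marker dropout bursts, non-gait arm-raise artifacts).
#'
#' The arm-swing law: at every frame the generator computes the expected
#' per-step turning angle from the path geometry, bins it exactly as the
#' feature pipeline does, converts the bin to a signed per-arm curvature
#' (outside arm positive, inside negative), and targets a shoulder-arm
#' angle standard deviation of
#' `arm_swing_sd_deg[emotion] + swing_slope[emotion] * curvature`,
#' optionally damped by `inside_damping` on the inside arm. The arm
#' oscillation is a sinusoid of amplitude `sqrt(2)` times the target SD, so
#' the within-bin SD of the shoulder-arm angle equals the target exactly
#' (up to sampling of whole swing cycles).
#'
#' @param path_kind One of `"circle"`, `"rounded_rectangle"`,
#'   `"random_circle"`.
#' @param direction `"CCW"`, `"CW"` or `"mixed"` (switches at random times).
#' @param radius Path radius in metres (corner radius for the rounded
#'   rectangle).
#' @param cadence Steps per second (both feet), default 1.8.
#' @param step_length Metres per step, default 0.65.
#' @param step_width Lateral distance between left and right footfall
#'   lines, metres.
#' @param arm_swing_sd_deg Named numeric: target shoulder-arm angle SD in
#'   degrees at zero curvature, per reported emotion.
#' @param swing_slope Named numeric: change in target SD per unit of signed
#'   curvature, per reported emotion.
#' @param inside_damping Multiplier (0, 1] applied to the inside arm's
#'   amplitude on curved path segments.
#' @param noise_sd Isotropic Gaussian noise SD added to every coordinate,
#'   metres.
#' @param gap_rate Expected marker-dropout bursts per minute (all markers
#'   lost for the burst duration).
#' @param gap_length_range Burst length range in frames.
#' @param artifact_rate Expected arm-raise events per minute.
#' @param duration_s Trial length in seconds.
#' @param switch_interval_s Range of times between direction switches for
#'   `direction = "mixed"`, seconds.
#' @param seed Integer seed; the trial is fully reproducible from it.
#' @return A list of class `walk_config`.
#' @export
walk_config <- function(path_kind = c("circle", "rounded_rectangle",
                                      "random_circle"),
                        direction = c("CCW", "CW", "mixed"),
                        radius = 2.5,
                        cadence = 1.8,
                        step_length = 0.65,
                        step_width = 0.04,
                        arm_swing_sd_deg = c(Happy = 4.5521,
                                             Neither = 3.8916,
                                             Sad = 3.1764),
                        swing_slope = c(Happy = 0.0259,
                                        Neither = 0.0017,
                                        Sad = 0.0038),
                        inside_damping = 1,
                        noise_sd = 0.001,
                        gap_rate = 1,
                        gap_length_range = c(10, 200),
                        artifact_rate = 0.5,
                        duration_s = 600,
                        switch_interval_s = c(45, 90),
                        seed = 1L) {
  path_kind <- match.arg(path_kind)
  direction <- match.arg(direction)
  stopifnot(radius > 0, cadence > 0, step_length > 0,
            inside_damping > 0, inside_damping <= 1,
            all(c("Happy", "Neither", "Sad") %in% names(arm_swing_sd_deg)),
            all(c("Happy", "Neither", "Sad") %in% names(swing_slope)))
  structure(list(
    path_kind = path_kind, direction = direction, radius = radius,
    cadence = cadence, step_length = step_length, step_width = step_width,
    arm_swing_sd_deg = arm_swing_sd_deg, swing_slope = swing_slope,
    inside_damping = inside_damping, noise_sd = noise_sd,
    gap_rate = gap_rate, gap_length_range = gap_length_range,
    artifact_rate = artifact_rate, duration_s = duration_s,
    switch_interval_s = switch_interval_s, seed = as.integer(seed)
  ), class = "walk_config")
}

# Static body-frame marker offsets: (forward, lateral-left, up), metres.
# The back markers sit laterally in line with the shoulder-back markers so
# that the shoulder-arm reference vector lies in the arm's sagittal swing
# plane; the shoulder-arm angle is then exactly linear in the swing phase.
.body_offsets <- function() {
  rbind(
    HeadTop           = c( 0.00,  0.00, 1.70),
    HeadFront         = c( 0.09,  0.00, 1.63),
    HeadSide          = c( 0.00,  0.09, 1.60),
    BackTop           = c(-0.09,  0.00, 1.46),
    Chest             = c( 0.09,  0.00, 1.35),
    BackLeft          = c(-0.12,  0.17, 1.24),
    BackRight         = c(-0.12, -0.17, 1.24),
    WaistLeftFront    = c( 0.10,  0.12, 1.00),
    WaistRightFront   = c( 0.10, -0.12, 1.00),
    WaistLeftBack     = c(-0.10,  0.11, 1.02),
    WaistRightBack    = c(-0.10, -0.11, 1.02),
    LeftShoulderBack  = c(-0.06,  0.17, 1.42),
    RightShoulderBack = c(-0.06, -0.17, 1.42),
    LeftShoulderTop   = c( 0.00,  0.18, 1.47),
    RightShoulderTop  = c( 0.00, -0.18, 1.47)
  )
}

# Per-frame signed turn rate (rad/s) along the configured path.
.turn_rate <- function(walk, t) {
  v <- walk$cadence * walk$step_length
  dir0 <- if (walk$direction == "CW") -1 else 1
  dirs <- rep(dir0, length(t))
  if (walk$direction == "mixed") {
    # direction flips at random times
    sw <- numeric(0)
    tt <- 0
    repeat {
      tt <- tt + stats::runif(1, walk$switch_interval_s[1],
                              walk$switch_interval_s[2])
      if (tt >= max(t)) break
      sw <- c(sw, tt)
    }
    flips <- findInterval(t, sw)
    dirs <- dir0 * (-1)^flips
  }
  base <- switch(walk$path_kind,
    circle = rep(v / walk$radius, length(t)),
    rounded_rectangle = {
      # two straights (4.0 m, 3.0 m) joined by quarter-circle corners
      rc <- min(walk$radius, 1.4)
      seg <- c(4.0, pi / 2 * rc, 3.0, pi / 2 * rc,
               4.0, pi / 2 * rc, 3.0, pi / 2 * rc)
      cum <- cumsum(seg)
      s <- (v * t) %% cum[8]
      idx <- findInterval(s, c(0, cum[-8]))
      ifelse(idx %% 2 == 0, v / rc, 0)
    },
    random_circle = {
      # slowly wandering radius
      g <- numeric(length(t))
      for (k in 1:3) {
        f <- stats::runif(1, 0.003, 0.02)
        ph <- stats::runif(1, 0, 2 * pi)
        a <- c(0.5, 0.35, 0.2)[k]
        g <- g + a * sin(2 * pi * f * t + ph)
      }
      v / (walk$radius * exp(0.5 * g))
    }
  )
  base * dirs
}

# Map a per-step turning angle (deg, signed) to the signed centre of its
# straightness bin, clamping beyond the catalogued range to +/-30.
.curvature_bin <- function(theta_deg) {
  mag <- abs(theta_deg)
  c_mag <- ifelse(mag < 5, 0, ifelse(mag < 15, 10, ifelse(mag < 25, 20, 30)))
  c_mag * sign(theta_deg) * (c_mag > 0)
}

#' Generate one synthetic walking trial
#'
#' Produces a 100 fps [marker_series()] of all 37 markers: a rigid torso
#' frame translating along the configured path with tangential heading,
#' alternating single-support stepping at the configured cadence and step
#' length, arm oscillation following the emotion- and curvature-dependent
#' swing law, plus optional coordinate noise, full-body dropout bursts and
#' arm-raise artifacts (hand/wrist elevated by 0.35-0.5 m for 1-2 s).
#'
#' Ground-truth attributes are attached for testing: `truth` (per-frame
#' step-turn angle, signed curvature bin, and per-arm target swing SD),
#' `artifacts` and `gaps` (event tables).
#'
#' @param walk A [walk_config()].
#' @param meta One-row metadata (see [trial_metadata()]); the reported
#'   emotion selects the swing law parameters.
#' @param fps Frames per second (default 100).
#' @param trim_guard_s The trial must be longer than twice this trimming
#'   window (default 60 s, matching [trim_trial()]); shorter configurations
#'   are refused because the trial would be empty after trimming. Set to 0
#'   for miniature test trials.
#' @return A [marker_series()] with truth attributes.
#' @export
generate_trial <- function(walk, meta, fps = 100, trim_guard_s = 60) {
  stopifnot(inherits(walk, "walk_config"), nrow(meta) == 1)
  if (walk$duration_s <= 2 * trim_guard_s) {
    stop("trial duration ", walk$duration_s, " s is not longer than twice ",
         "the trimming window (", trim_guard_s, " s); trial would be empty ",
         "after trimming", call. = FALSE)
  }
  set.seed(walk$seed)
  n <- as.integer(round(walk$duration_s * fps))
  t <- (seq_len(n) - 1) / fps
  emotion <- meta$reported_emotion[1]

  # --- path -----------------------------------------------------------
  omega <- .turn_rate(walk, t)                     # rad/s, +ve = CCW
  v <- walk$cadence * walk$step_length             # m/s
  psi <- cumsum(omega) / fps                       # heading, rad
  px <- cumsum(v * cos(psi)) / fps
  pz <- cumsum(v * sin(psi)) / fps
  ux <- cos(psi); uz <- sin(psi)                   # forward unit vector
  lx <- -sin(psi); lz <- cos(psi)                  # left unit vector

  # --- emotion / curvature swing law ----------------------------------
  # Per-step turning angle as the downstream straightness statistic sees
  # it: the step-triple construction integrates heading change over a
  # window of about two steps, so the turn is averaged over +/- one step
  # rather than taken instantaneously. This keeps the emulated swing
  # amplitude aligned with the measured straightness bin at path
  # transitions (corner entries, radius drift, direction switches).
  L <- max(1L, as.integer(round(fps / walk$cadence)))
  il <- pmax(seq_len(n) - L, 1L)
  ir <- pmin(seq_len(n) + L, n)
  step_turn <- (psi[ir] - psi[il]) / ((ir - il) / fps) /
    walk$cadence * 180 / pi                        # deg per step
  cbin <- .curvature_bin(step_turn)                # signed bin centre
  base <- walk$arm_swing_sd_deg[[emotion]]
  slope <- walk$swing_slope[[emotion]]
  # swing responds to the straightness bin the walker is in: per-arm
  # signed curvature with the outside arm positive, so the measured
  # within-bin SD equals the law evaluated at the bin centre
  curv_left <- -cbin
  curv_right <- cbin
  damp_left <- ifelse(cbin > 0, walk$inside_damping, 1)
  damp_right <- ifelse(cbin < 0, walk$inside_damping, 1)
  target_left <- pmax(damp_left * (base + slope * curv_left), 0.1)
  target_right <- pmax(damp_right * (base + slope * curv_right), 0.1)

  stride_ph <- pi * walk$cadence * t               # stride phase (rad)
  phi_left <- sqrt(2) * target_left * pi / 180 * sin(stride_ph + pi)
  phi_right <- sqrt(2) * target_right * pi / 180 * sin(stride_ph)

  # --- assemble markers (body frame: fwd, lat-left, up) ---------------
  markers <- marker_vocabulary()
  coords <- array(NA_real_, dim = c(n, length(markers), 3),
                  dimnames = list(NULL, markers, c("X", "Y", "Z")))
  place <- function(name, fwd, lat, up) {
    coords[, name, "X"] <<- px + fwd * ux + lat * lx
    coords[, name, "Z"] <<- pz + fwd * uz + lat * lz
    coords[, name, "Y"] <<- up
  }

  bob <- 0.012 * sin(2 * stride_ph)                # vertical CoM bob
  off <- .body_offsets()
  for (m in rownames(off)) place(m, off[m, 1], off[m, 2], off[m, 3] + bob)

  # head nod (emotion-independent): pitch about a neck pivot
  nod <- 0.03 * sin(2 * stride_ph)                 # rad
  neck_up <- 1.50
  for (m in c("HeadTop", "HeadFront", "HeadSide")) {
    f0 <- off[m, 1]; u0 <- off[m, 3] - neck_up
    place(m, f0 * cos(nod) + u0 * sin(nod), off[m, 2],
          neck_up + bob + u0 * cos(nod) - f0 * sin(nod))
  }

  # legs: feet oscillate fore-aft, markers interpolated toward the hip
  foot_f <- (walk$step_length / 2) * sin(stride_ph)     # left foot forward
  lift_left <- 0.05 * pmax(0, cos(stride_ph))
  lift_right <- 0.05 * pmax(0, -cos(stride_ph))
  wl <- walk$step_width / 2
  leg <- function(side, f, lift) {
    s <- if (side == "Left") 1 else -1
    place(paste0(side, "AnkleOut"), f, s * wl, 0.09 + lift)
    place(paste0(side, "ToeOut"), f + 0.13, s * (wl + 0.03), 0.05 + lift)
    place(paste0(side, "ToeIn"), f + 0.13, s * (wl - 0.03), 0.05 + lift)
    place(paste0(side, "Shin"), 0.70 * f, s * (wl + 0.02), 0.28 + 0.5 * lift)
    place(paste0(side, "KneeOut"), 0.50 * f, s * (wl + 0.04), 0.50 + 0.3 * lift)
    place(paste0(side, "ThighFront"), 0.25 * f + 0.06, s * 0.10, 0.74)
  }
  leg("Left", foot_f, lift_left)
  leg("Right", -foot_f, lift_right)

  # arms: rigid pendulum from the shoulder-back pivot, swinging in the
  # sagittal plane; forearm carries a fixed elbow flexion
  arm <- function(side, phi) {
    s <- if (side == "Left") 1 else -1
    pv_f <- -0.06; pv_l <- s * 0.17; pv_u <- 1.42
    dirf <- sin(phi); diru <- -cos(phi)
    phif <- phi + 0.35
    dirff <- sin(phif); dirfu <- -cos(phif)
    place(paste0(side, "UpperArmHigh"),
          pv_f + 0.16 * dirf, pv_l, pv_u + bob + 0.16 * diru)
    el_f <- pv_f + 0.30 * dirf; el_u <- pv_u + 0.30 * diru
    place(paste0(side, "ElbowOut"), el_f, pv_l + s * 0.02, el_u + bob)
    place(paste0(side, "WristOut"),
          el_f + 0.26 * dirff, pv_l + s * 0.01, el_u + bob + 0.26 * dirfu)
    place(paste0(side, "WristIn"),
          el_f + 0.26 * dirff, pv_l - s * 0.05, el_u + bob + 0.26 * dirfu)
    place(paste0(side, "HandOut"),
          el_f + 0.34 * dirff, pv_l + s * 0.01, el_u + bob + 0.34 * dirfu)
  }
  arm("Left", phi_left)
  arm("Right", phi_right)

  # --- arm-raise artifacts --------------------------------------------
  n_art <- stats::rpois(1, walk$artifact_rate * walk$duration_s / 60)
  artifacts <- data.frame(start = integer(0), end = integer(0),
                          core_start = integer(0), core_end = integer(0),
                          side = character(0), height = numeric(0))
  if (n_art > 0) {
    for (k in seq_len(n_art)) {
      # raise-hold-lower: 15% ramp up, 70% plateau, 15% ramp down
      dur <- as.integer(stats::runif(1, 1, 2) * fps)
      start <- as.integer(stats::runif(1, 1, n - dur))
      side <- sample(c("Left", "Right"), 1)
      h <- stats::runif(1, 0.35, 0.5)
      idx <- start:(start + dur - 1)
      u <- seq_along(idx) / length(idx)
      ramp <- pmin(1, pmin(u, 1 - u) / 0.15)
      bump <- h * sin(pmin(1, ramp) * pi / 2)^2
      for (m in paste0(side, c("HandOut", "WristOut", "WristIn"))) {
        coords[idx, m, "Y"] <- coords[idx, m, "Y"] + bump
      }
      coords[idx, paste0(side, "ElbowOut"), "Y"] <-
        coords[idx, paste0(side, "ElbowOut"), "Y"] + 0.4 * bump
      core <- range(which(bump >= 0.3))
      artifacts <- rbind(artifacts,
                         data.frame(start = start - 1L,
                                    end = start + dur - 2L,
                                    core_start = start - 1L + core[1] - 1L,
                                    core_end = start - 1L + core[2] - 1L,
                                    side = side, height = h))
    }
  }

  # --- dropout bursts (all markers occluded) --------------------------
  n_gap <- stats::rpois(1, walk$gap_rate * walk$duration_s / 60)
  gaps <- data.frame(start = integer(0), end = integer(0))
  if (n_gap > 0) {
    for (k in seq_len(n_gap)) {
      len <- as.integer(stats::runif(1, walk$gap_length_range[1],
                                     walk$gap_length_range[2] + 1))
      start <- as.integer(stats::runif(1, 1, max(2, n - len)))
      coords[start:(start + len - 1), , ] <- NA_real_
      gaps <- rbind(gaps, data.frame(start = start - 1L,
                                     end = start + len - 2L))
    }
  }

  # --- coordinate noise ------------------------------------------------
  if (walk$noise_sd > 0) {
    ok <- !is.na(coords)
    coords[ok] <- coords[ok] + stats::rnorm(sum(ok), 0, walk$noise_sd)
  }

  series <- marker_series(meta$trial_id[1], fps, seq_len(n) - 1L, coords)
  attr(series, "walk") <- walk
  attr(series, "truth") <- list(
    step_turn_deg = step_turn, curvature_bin = cbin,
    target_sd_left = target_left, target_sd_right = target_right
  )
  attr(series, "artifacts") <- artifacts
  attr(series, "gaps") <- gaps
  series
}

#' Cohort configuration for the synthetic study
#'
#' Defaults reproduce the study design being emulated: 49 subjects
#' (41 male, 8 female) each walking three trials (Neutral, Positive,
#' Negative stimulus), 147 trials total with one flagged corrupted, and
#' self-reported emotion labels distributed as in the observed
#' stimulus-by-report contingency (column totals 44 Happy / 44 Sad /
#' 59 Neither).
#'
#' @param n_subjects Number of subjects (default 49).
#' @param emotions_per_subject Expected-emotion (stimulus) labels each
#'   subject walks under.
#' @param confusion Row-stochastic matrix mapping stimulus (rows Positive,
#'   Negative, Neutral) to reported emotion (columns Happy, Sad, Neither).
#' @param exact_confusion If `TRUE` (default) and `n_subjects` matches the
#'   contingency row totals, reported labels are assigned to reproduce the
#'   contingency counts exactly (randomised over subjects); otherwise they
#'   are drawn per trial from `confusion`.
#' @param female_fraction Fraction of female subjects (default 8/49).
#' @param corrupt_one Flag one random trial as corrupted (default `TRUE`).
#' @param subject_swing_sd Between-subject SD (degrees) of an additive
#'   per-subject offset on the arm-swing base levels.
#' @param trial_duration Trial length, seconds (default 600).
#' @param radius_range Per-subject path radius drawn log-uniformly from
#'   this range, metres; the default spans all seven straightness bins.
#' @param seed Master integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 49,
                          emotions_per_subject = c("Neutral", "Positive",
                                                   "Negative"),
                          confusion = default_confusion(),
                          exact_confusion = TRUE,
                          female_fraction = 8 / 49,
                          corrupt_one = TRUE,
                          subject_swing_sd = 0.3,
                          trial_duration = 600,
                          radius_range = c(1.3, 9),
                          seed = 1L) {
  stopifnot(n_subjects >= 1,
            all(abs(rowSums(confusion) - 1) < 1e-8))
  structure(list(
    n_subjects = as.integer(n_subjects),
    emotions_per_subject = emotions_per_subject,
    confusion = confusion, exact_confusion = exact_confusion,
    female_fraction = female_fraction, corrupt_one = corrupt_one,
    subject_swing_sd = subject_swing_sd,
    trial_duration = trial_duration, radius_range = radius_range,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default stimulus-to-reported-emotion confusion table
#'
#' The observed contingency of reported emotion by video stimulus,
#' normalised to row proportions. Rows: Positive, Negative, Neutral
#' stimulus; columns: Happy, Sad, Neither report. The unnormalised counts
#' are available as `attr(,"counts")`.
#'
#' @return A 3x3 row-stochastic matrix.
#' @export
default_confusion <- function() {
  counts <- matrix(c(12, 23, 14,
                     13, 19, 17,
                     19, 2, 28),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("Positive", "Negative", "Neutral"),
                                   c("Happy", "Sad", "Neither")))
  out <- counts / rowSums(counts)
  attr(out, "counts") <- counts
  out
}

.stimulus_expected <- c(Neutral = "Neutral", Positive = "Positive",
                        Negative = "Negative")

#' Generate a synthetic walking cohort
#'
#' Draws per-subject walking styles (path kind, direction, cadence, step
#' length, radius — held fixed across that subject's trials), assigns
#' reported-emotion labels from the confusion table, flags one corrupted
#' trial, and derives an independent seed for every trial so each can be
#' generated reproducibly on demand.
#'
#' @param cfg A [cohort_config()].
#' @param walk_defaults A [walk_config()] supplying every per-trial field
#'   not sampled per subject.
#' @param materialize If `TRUE`, generate and return every trial's
#'   [marker_series()] (memory-heavy; intended for small test cohorts).
#' @return A list with `meta` (metadata data.frame, one row per trial),
#'   `walks` (list of per-trial [walk_config()]s) and `series` (list of
#'   [marker_series()] or `NULL`).
#' @export
generate_cohort <- function(cfg, walk_defaults = walk_config(),
                            materialize = FALSE) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  ns <- cfg$n_subjects
  n_female <- round(cfg$female_fraction * ns)
  genders <- rep("Male", ns)
  if (n_female > 0) genders[sample(ns, n_female)] <- "Female"

  styles <- data.frame(
    subject = sprintf("S%03d", seq_len(ns)),
    gender = genders,
    path_kind = sample(c("circle", "rounded_rectangle", "random_circle"),
                       ns, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
    direction = sample(c("CCW", "CW", "mixed"), ns, replace = TRUE,
                       prob = c(0.68, 0.14, 0.18)),
    cadence = pmin(pmax(stats::rnorm(ns, walk_defaults$cadence, 0.08),
                        1.5), 2.1),
    step_length = pmin(pmax(stats::rnorm(ns, walk_defaults$step_length,
                                         0.04), 0.5), 0.8),
    radius = exp(stats::runif(ns, log(cfg$radius_range[1]),
                              log(cfg$radius_range[2]))),
    swing_offset = stats::rnorm(ns, 0, cfg$subject_swing_sd),
    stringsAsFactors = FALSE
  )

  stimuli <- cfg$emotions_per_subject
  n_trials <- ns * length(stimuli)

  # reported emotion per (subject, stimulus)
  reported <- matrix(NA_character_, nrow = ns, ncol = length(stimuli))
  counts <- attr(cfg$confusion, "counts")
  use_exact <- isTRUE(cfg$exact_confusion) && !is.null(counts) &&
    all(rowSums(counts) == ns)
  for (j in seq_along(stimuli)) {
    row <- .stimulus_expected[[stimuli[j]]]
    if (use_exact) {
      pool <- rep(colnames(counts), counts[row, ])
      reported[, j] <- sample(pool, ns)
    } else {
      reported[, j] <- sample(colnames(cfg$confusion), ns, replace = TRUE,
                              prob = cfg$confusion[row, ])
    }
  }

  meta_rows <- list()
  walks <- list()
  idx <- 0L
  for (i in seq_len(ns)) {
    for (j in seq_along(stimuli)) {
      idx <- idx + 1L
      tid <- sprintf("%s_T%d", styles$subject[i], j)
      meta_rows[[idx]] <- trial_metadata(
        trial_id = tid, subject_id = styles$subject[i],
        expected_emotion = .stimulus_expected[[stimuli[j]]],
        reported_emotion = reported[i, j],
        gender = styles$gender[i], corrupted = FALSE
      )
      wd <- walk_defaults
      swing <- wd$arm_swing_sd_deg + styles$swing_offset[i]
      walks[[idx]] <- walk_config(
        path_kind = styles$path_kind[i], direction = styles$direction[i],
        radius = styles$radius[i], cadence = styles$cadence[i],
        step_length = styles$step_length[i], step_width = wd$step_width,
        arm_swing_sd_deg = swing, swing_slope = wd$swing_slope,
        inside_damping = wd$inside_damping, noise_sd = wd$noise_sd,
        gap_rate = wd$gap_rate, gap_length_range = wd$gap_length_range,
        artifact_rate = wd$artifact_rate,
        duration_s = cfg$trial_duration,
        switch_interval_s = wd$switch_interval_s,
        seed = (cfg$seed * 10007L + idx * 101L) %% 2147483629L
      )
    }
  }
  meta <- do.call(rbind, meta_rows)
  if (isTRUE(cfg$corrupt_one) && n_trials > 1) {
    meta$corrupted[sample(n_trials, 1)] <- TRUE
  }
  names(walks) <- meta$trial_id

  series <- NULL
  if (materialize) {
    series <- lapply(seq_len(n_trials), function(k) {
      generate_trial(walks[[k]], meta[k, , drop = FALSE], trim_guard_s = 0)
    })
    names(series) <- meta$trial_id
  }
  list(meta = meta, walks = walks, series = series)
}

#' Simulate an arm-swing table directly (statistics-level simulator)
#'
#' Bypasses trajectory generation: draws per-trial arm-swing magnitudes
#' from the linear curvature law plus Gaussian trial-level noise, producing
#' the same table layout as [build_arm_swing_table()]. Used for
#' calibration experiments (type-I error, power) where thousands of
#' replicates would make full trajectory simulation wasteful.
#'
#' @param n_per_emotion Named integer vector of trial counts per reported
#'   emotion.
#' @param base,slope Named numerics (per emotion): intercept (degrees) and
#'   slope (degrees per curvature unit) of the swing law.
#' @param sigma Trial-level Gaussian SD of the swing magnitude, degrees.
#' @param curvature_magnitudes Bin magnitudes each trial visits.
#' @param female_fraction Fraction of trials from female subjects.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `trial_id, straightness_group,
#'   curvature, arm_side, swing_sd_deg, reported_emotion, expected_emotion,
#'   gender`.
#' @export
simulate_arm_swing_table <- function(n_per_emotion = c(Happy = 44, Sad = 44,
                                                       Neither = 59),
                                     base = c(Happy = 4.5521,
                                              Neither = 3.8916,
                                              Sad = 3.1764),
                                     slope = c(Happy = 0.0259,
                                               Neither = 0.0017,
                                               Sad = 0.0038),
                                     sigma = 0.3,
                                     curvature_magnitudes = c(0, 10, 20, 30),
                                     female_fraction = 8 / 49,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- straightness_groups()
  rows <- list()
  tid <- 0L
  for (emo in names(n_per_emotion)) {
    for (k in seq_len(n_per_emotion[[emo]])) {
      tid <- tid + 1L
      gender <- if (stats::runif(1) < female_fraction) "Female" else "Male"
      trial_noise <- stats::rnorm(1, 0, sigma)
      # the trial walks one direction; visited groups share that sign
      dir <- sample(c(-1, 1), 1)
      g <- groups[groups$magnitude %in% curvature_magnitudes &
                    (groups$direction == "straight" |
                       groups$direction == ifelse(dir > 0, "CCW", "CW")), ]
      for (gi in seq_len(nrow(g))) {
        for (side in c("left", "right")) {
          curv <- curvature_from_group(g$label[gi], side)
          y <- base[[emo]] + slope[[emo]] * curv + trial_noise +
            stats::rnorm(1, 0, sigma / 3)
          rows[[length(rows) + 1L]] <- data.frame(
            trial_id = sprintf("sim%04d", tid),
            straightness_group = g$label[gi], curvature = curv,
            arm_side = side, swing_sd_deg = y, n_frames = 1000L,
            reported_emotion = emo, expected_emotion = "Neutral",
            gender = gender, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}
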