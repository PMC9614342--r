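#' Default feature-extraction parameters
#'
#' All thresholds of the preprocessing and feature-extraction stages in one
#' place. Defaults are the analysis constants: 60 s trimming, 2-SD arm
#' filter, 25-frame gap threshold, 50-frame minimum chunk, 3-step minimum,
#' Savitzky-Golay window 31 / order 3, 0.25 s minimum peak separation and
#' 0.02 m minimum peak prominence.
#'
#' @param ... Named overrides of any default.
#' @return A named list of parameters.
#' @export
feature_params <- function(...) {
  p <- list(
    trim_seconds = 60,
    sd_multiplier = 2,
    gap_threshold = 25,
    min_chunk = 50,
    sg_window = 31,
    sg_order = 3,
    min_step_separation_s = 0.25,
    min_prominence = 0.02,
    min_steps = 3,
    step_point = "leading_foot",
    direction_threshold = 0.9
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(dots)] <- dots
  p
}

#' Top-view inter-foot distance
#'
#' Euclidean distance between the left and right ankle markers in the
#' horizontal (X, Z) plane, per kept frame of a chunk. Vertical (Y)
#' separation is ignored.
#'
#' @param chunk A chunk from [split_chunks()] (straightness purpose).
#' @param series The trimmed [marker_series()].
#' @return Numeric vector, one distance (m) per kept frame.
#' @export
interfoot_distance <- function(chunk, series) {
  idx <- match(chunk$frames, series$frames)
  L <- marker_xyz(series, "LeftAnkleOut")[idx, , drop = FALSE]
  R <- marker_xyz(series, "RightAnkleOut")[idx, , drop = FALSE]
  sqrt((L[, "X"] - R[, "X"])^2 + (L[, "Z"] - R[, "Z"])^2)
}

#' Savitzky-Golay smoothing of a per-frame signal
#'
#' Local polynomial least-squares smoothing. The default window (31
#' frames, 0.31 s at 100 fps) and order (3) preserve cadence-rate peaks
#' (~2 Hz) while suppressing frame-level jitter. A polynomial of degree
#' at most `order` passes through unchanged.
#'
#' @param x Numeric signal.
#' @param window Filter window length, frames (odd).
#' @param order Polynomial order.
#' @return Smoothed signal; if `x` is shorter than `window` it is returned
#'   unchanged with a warning.
#' @export
smooth_distance <- function(x, window = 31, order = 3) {
  if (length(x) < window) {
    warning("signal shorter than smoothing window (", length(x), " < ",
            window, "); returned unsmoothed", call. = FALSE)
    return(x)
  }
  as.numeric(signal::sgolayfilt(x, p = order, n = window))
}

#' Prominence-aware local-maximum detection
#'
#' Finds local maxima, computes each peak's topographic prominence (height
#' above the higher of the two bases, where a base is the lowest point
#' between the peak and the nearest higher point, or the signal end), and
#' enforces a minimum peak-to-peak distance by greedily keeping higher
#' peaks first.
#'
#' @param x Numeric signal.
#' @param min_distance Minimum separation between kept peaks, samples.
#' @param min_prominence Minimum prominence in signal units.
#' @return Integer indices of kept peaks, increasing.
#' @export
find_peaks <- function(x, min_distance = 1, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  # local maxima with plateau handling: rising then falling
  s <- sign(d)
  # propagate sign through zero runs so flat plateau tops count once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  cand <- which(diff(s) < 0) + 1L
  cand <- cand[cand > 1 & cand < n]
  if (length(cand) == 0) return(integer(0))

  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1)]
    higher_l <- which(left > h)
    lo_l <- if (length(higher_l) == 0) min(left) else
      min(left[(max(higher_l) + 1):(i - 1)])
    right <- x[(i + 1):n]
    higher_r <- which(right > h)
    lo_r <- if (length(higher_r) == 0) min(right) else
      min(right[seq_len(min(higher_r) - 1)])
    h - max(lo_l, lo_r)
  }, numeric(1))

  keep <- cand[prom >= min_prominence]
  if (length(keep) <= 1) return(keep)
  # greedy minimum-distance enforcement, highest peaks first
  ord <- keep[order(x[keep], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in ord) {
    if (all(abs(i - chosen) >= min_distance)) chosen <- c(chosen, i)
  }
  sort(chosen)
}

#' Detect walking steps from the smoothed inter-foot distance
#'
#' Each peak of the inter-foot distance is a moment of full stride and
#' becomes a step event. The event's side is the leading foot (the one
#' further forward along the current walking direction) and its location
#' is that foot's top-view (X, Z) position, or the inter-foot midpoint if
#' `step_point = "midpoint"`.
#'
#' Chunks yielding fewer than `min_steps` steps are unusable for
#' straightness and return zero rows.
#'
#' @param smoothed Smoothed inter-foot distance (from
#'   [smooth_distance()]).
#' @param chunk The chunk the signal came from.
#' @param series The trimmed [marker_series()].
#' @param min_separation_s Minimum step separation, seconds.
#' @param min_prominence Minimum peak prominence, metres.
#' @param min_steps Minimum steps for a usable chunk (default 3).
#' @param step_point `"leading_foot"` or `"midpoint"`.
#' @return A data.frame of step events: `frame`, `side`, `x`, `z`.
#' @export
detect_steps <- function(smoothed, chunk, series,
                         min_separation_s = 0.25, min_prominence = 0.02,
                         min_steps = 3, step_point = "leading_foot") {
  empty <- data.frame(frame = integer(0), side = character(0),
                      x = numeric(0), z = numeric(0))
  idx <- match(chunk$frames, series$frames)
  peaks <- find_peaks(smoothed,
                      min_distance = round(min_separation_s * series$fps),
                      min_prominence = min_prominence)
  if (length(peaks) < min_steps) return(empty)

  L <- marker_xyz(series, "LeftAnkleOut")[idx, c("X", "Z"), drop = FALSE]
  R <- marker_xyz(series, "RightAnkleOut")[idx, c("X", "Z"), drop = FALSE]
  mid <- (L + R) / 2
  n <- nrow(mid)
  steps <- lapply(peaks, function(i) {
    a <- max(1L, i - 30L); b <- min(n, i + 30L)
    heading <- mid[b, ] - mid[a, ]
    fwd_L <- sum((L[i, ] - mid[i, ]) * heading)
    side <- if (fwd_L >= 0) "left" else "right"
    pt <- switch(step_point,
                 leading_foot = if (side == "left") L[i, ] else R[i, ],
                 midpoint = mid[i, ],
                 stop("unknown step_point '", step_point, "'"))
    data.frame(frame = chunk$frames[i], side = side,
               x = pt[["X"]], z = pt[["Z"]])
  })
  do.call(rbind, steps)
}

#' Signed straightness angles from consecutive step triples
#'
#' For steps k, k+1, k+2 the straightness is the signed planar angle from
#' the first step vector (step k to k+1) to the second (k+1 to k+2),
#' measured in the top-view (X, Z) plane. Positive angles are
#' counter-clockwise turning, negative clockwise; collinear steps give 0.
#'
#' @param steps Step events from [detect_steps()] (at least 3 rows).
#' @return A data.frame with one row per triple: `frame_start`,
#'   `frame_mid`, `frame_end` (frames of steps k, k+1, k+2) and `theta`
#'   (degrees, in (-180, 180]).
#' @export
straightness_angles <- function(steps) {
  m <- nrow(steps)
  out <- data.frame(frame_start = integer(0), frame_mid = integer(0),
                    frame_end = integer(0), theta = numeric(0))
  if (m < 3) return(out)
  v1x <- steps$x[2:(m - 1)] - steps$x[1:(m - 2)]
  v1z <- steps$z[2:(m - 1)] - steps$z[1:(m - 2)]
  v2x <- steps$x[3:m] - steps$x[2:(m - 1)]
  v2z <- steps$z[3:m] - steps$z[2:(m - 1)]
  cross <- v1x * v2z - v1z * v2x
  dot <- v1x * v2x + v1z * v2z
  theta <- atan2(cross, dot) * 180 / pi
  zero <- (v1x^2 + v1z^2) == 0 | (v2x^2 + v2z^2) == 0
  if (any(zero)) {
    warning(sum(zero), " step triple(s) with zero-length step vector skipped",
            call. = FALSE)
  }
  data.frame(frame_start = steps$frame[1:(m - 2)],
             frame_mid = steps$frame[2:(m - 1)],
             frame_end = steps$frame[3:m],
             theta = theta)[!zero, , drop = FALSE]
}

#' Assign straightness values to frames
#'
#' Every frame spanned by a step triple receives that triple's
#' straightness; frames spanned by two consecutive (overlapping) triples
#' receive the average of the two values. Frames before the first step or
#' after the last receive none.
#'
#' @param angles Triple table from [straightness_angles()].
#' @return A data.frame `frame`, `theta` (degrees), one row per covered
#'   frame.
#' @export
assign_straightness <- function(angles) {
  if (nrow(angles) == 0) {
    return(data.frame(frame = integer(0), theta = numeric(0)))
  }
  f0 <- min(angles$frame_start)
  f1 <- max(angles$frame_end)
  acc <- numeric(f1 - f0 + 1)
  cnt <- integer(f1 - f0 + 1)
  last <- nrow(angles)
  for (k in seq_len(last)) {
    # half-open span [start, end) so adjoining triples contribute exactly
    # two values to their shared frames; the final triple keeps its
    # endpoint frame
    hi <- if (k == last) angles$frame_end[k] else angles$frame_end[k] - 1L
    span <- (angles$frame_start[k]:hi) - f0 + 1L
    acc[span] <- acc[span] + angles$theta[k]
    cnt[span] <- cnt[span] + 1L
  }
  covered <- cnt > 0
  data.frame(frame = (f0:f1)[covered],
             theta = acc[covered] / cnt[covered])
}

#' Bin a straightness value into one of the seven groups
#'
#' Half-open 10-degree bins spanning \[-35, 35): a value of 0 falls in
#' "-5 to 5", 5 falls in "5 to 15", and values outside the range are
#' unbinned (`NA`).
#'
#' @param theta Numeric vector of straightness angles, degrees.
#' @return Character vector of group labels (`NA` outside the range).
#' @export
bin_straightness <- function(theta) {
  g <- straightness_groups()
  idx <- findInterval(theta, c(g$lo, 35))
  idx[idx < 1 | idx > 7] <- NA_integer_
  g$label[idx]
}

#' Compute body-part angles for a set of frames
#'
#' The 3-D angle at each definition's vertex marker between the vectors to
#' its two terminal markers, via the arc-cosine of the normalised dot
#' product; in degrees, in \[0, 180\]. The angle is missing wherever any
#' of the three markers is unobserved or a vector has zero length.
#'
#' @param series A [marker_series()].
#' @param frames Frame indices to evaluate (default: all frames).
#' @param defs Angle catalogue (default [angle_definitions()]).
#' @return Numeric matrix `length(frames) x nrow(defs)`; columns named by
#'   angle index.
#' @export
compute_angles <- function(series, frames = series$frames,
                           defs = angle_definitions()) {
  idx <- match(frames, series$frames)
  if (anyNA(idx)) stop("some requested frames are not in the series")
  out <- matrix(NA_real_, nrow = length(frames), ncol = nrow(defs),
                dimnames = list(NULL, as.character(defs$index)))
  n_zero <- 0L
  for (j in seq_len(nrow(defs))) {
    A <- series$coords[idx, defs$terminal1[j], , drop = TRUE] -
      series$coords[idx, defs$vertex[j], , drop = TRUE]
    B <- series$coords[idx, defs$terminal2[j], , drop = TRUE] -
      series$coords[idx, defs$vertex[j], , drop = TRUE]
    if (is.null(dim(A))) { A <- matrix(A, ncol = 3); B <- matrix(B, ncol = 3) }
    na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
    zero <- !is.na(na) & !is.na(nb) & (na == 0 | nb == 0)
    n_zero <- n_zero + sum(zero)
    cosv <- rowSums(A * B) / (na * nb)
    cosv[zero] <- NA_real_
    cosv <- pmin(1, pmax(-1, cosv))
    out[, j] <- acos(cosv) * 180 / pi
  }
  if (n_zero > 0) {
    warning(n_zero, " zero-length vertex vector(s); angle set to missing",
            call. = FALSE)
  }
  out
}

#' Aggregate angle features by straightness group
#'
#' Joins the per-frame straightness series with the per-frame angle
#' matrix and computes, for every (straightness group, angle index) cell,
#' the mean and sample standard deviation over frames holding both a
#' straightness bin and a valid angle value. Cells with fewer than two
#' such frames are omitted (both moments must be defined).
#'
#' @param straightness Data.frame `frame`, `theta` from
#'   [assign_straightness()] (all chunks combined).
#' @param angles Matrix from [compute_angles()].
#' @param angle_frames Frame indices corresponding to the rows of
#'   `angles`.
#' @param trial_id Trial identifier attached to the output rows.
#' @return A data.frame `trial_id, straightness_group, angle_index,
#'   mean_deg, sd_deg, n_frames`.
#' @export
aggregate_features <- function(straightness, angles, angle_frames,
                               trial_id) {
  empty <- data.frame(trial_id = character(0),
                      straightness_group = character(0),
                      angle_index = integer(0), mean_deg = numeric(0),
                      sd_deg = numeric(0), n_frames = integer(0))
  if (nrow(straightness) == 0 || length(angle_frames) == 0) return(empty)
  common <- intersect(straightness$frame, angle_frames)
  if (length(common) == 0) return(empty)
  th <- straightness$theta[match(common, straightness$frame)]
  grp <- bin_straightness(th)
  ok <- !is.na(grp)
  if (!any(ok)) return(empty)
  ang <- angles[match(common, angle_frames), , drop = FALSE][ok, ,
                                                             drop = FALSE]
  grp <- grp[ok]
  dt <- data.table::data.table(group = rep(grp, ncol(ang)),
                               angle_index = rep(as.integer(colnames(ang)),
                                                 each = nrow(ang)),
                               value = as.vector(ang))
  dt <- dt[!is.na(dt$value)]
  agg <- dt[, list(mean_deg = mean(value), sd_deg = stats::sd(value),
                   n_frames = .N), by = c("group", "angle_index")]
  agg <- agg[agg$n_frames >= 2L]
  res <- data.frame(trial_id = trial_id,
                    straightness_group = agg$group,
                    angle_index = agg$angle_index,
                    mean_deg = agg$mean_deg, sd_deg = agg$sd_deg,
                    n_frames = agg$n_frames, stringsAsFactors = FALSE)
  res[order(match(res$straightness_group, straightness_groups()$label),
            res$angle_index), , drop = FALSE]
}

#' Convert a straightness group to a signed per-arm curvature
#'
#' On a curved path the outside arm takes the positive curvature sign and
#' the inside arm the negative sign. Clockwise groups (negative
#' straightness) have the left arm outside; counter-clockwise groups have
#' the left arm inside. The straight group maps to 0 for both arms.
#'
#' @param group Character vector of group labels (see
#'   [straightness_groups()]).
#' @param arm `"left"` or `"right"` (recycled).
#' @return Integer curvature values in \{-30, -20, -10, 0, 10, 20, 30\}.
#' @export
curvature_from_group <- function(group, arm) {
  g <- straightness_groups()
  i <- match(group, g$label)
  if (anyNA(i)) {
    stop("unknown straightness group(s): ",
         paste(unique(group[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  stopifnot(all(arm %in% c("left", "right")))
  mag <- g$magnitude[i]
  dirn <- g$direction[i]
  sign_left <- ifelse(dirn == "straight", 0, ifelse(dirn == "CW", 1, -1))
  out <- ifelse(rep(arm, length.out = length(i)) == "left",
                sign_left * mag, -sign_left * mag)
  as.integer(out)
}

#' Build the arm-swing magnitude table
#'
#' One row per (trial, straightness group, arm side): the arm-swing
#' magnitude is the within-group SD of the shoulder-arm angle (catalogue
#' index 19 for the left arm, 20 for the right), the curvature is the
#' Table-8-style signed conversion of the group, and the trial's reported
#' emotion, expected emotion and gender are attached.
#'
#' @param features An aggregated feature table ([aggregate_features()]
#'   rows, possibly many trials).
#' @param meta Trial metadata ([trial_metadata()]).
#' @param min_frames Minimum frame support for a swing-magnitude row
#'   (default 120, about one full arm-swing cycle at usual cadence: an SD
#'   estimated from less than one cycle does not measure swing amplitude).
#' @return A data.frame `trial_id, straightness_group, curvature,
#'   arm_side, swing_sd_deg, n_frames, reported_emotion, expected_emotion,
#'   gender`.
#' @export
build_arm_swing_table <- function(features, meta, min_frames = 120) {
  rows <- features[features$angle_index %in% c(19L, 20L) &
                     features$n_frames >= min_frames, , drop = FALSE]
  if (nrow(rows) == 0) {
    return(data.frame(trial_id = character(0),
                      straightness_group = character(0),
                      curvature = integer(0), arm_side = character(0),
                      swing_sd_deg = numeric(0), n_frames = integer(0),
                      reported_emotion = character(0),
                      expected_emotion = character(0),
                      gender = character(0)))
  }
  side <- ifelse(rows$angle_index == 19L, "left", "right")
  mi <- match(rows$trial_id, meta$trial_id)
  data.frame(
    trial_id = rows$trial_id,
    straightness_group = rows$straightness_group,
    curvature = curvature_from_group(rows$straightness_group, side),
    arm_side = side,
    swing_sd_deg = rows$sd_deg,
    n_frames = rows$n_frames,
    reported_emotion = meta$reported_emotion[mi],
    expected_emotion = meta$expected_emotion[mi],
    gender = meta$gender[mi],
    stringsAsFactors = FALSE
  )
}

#' Classify a trial's overall walking direction
#'
#' Counts the curved binned frames (5 <= |theta| < 35). If at least
#' `threshold` of them turn counter-clockwise the trial is CCW; if at
#' least `threshold` turn clockwise it is CW; otherwise (or if the trial
#' is all-straight) it is "both".
#'
#' @param straightness Data.frame `frame`, `theta`.
#' @param threshold Majority fraction (default 0.9).
#' @return One of `"CW"`, `"CCW"`, `"both"`.
#' @export
classify_walk_direction <- function(straightness, threshold = 0.9) {
  th <- straightness$theta
  curved <- th[abs(th) >= 5 & abs(th) < 35]
  if (length(curved) == 0) {
    warning("no curved frames; direction reported as 'both'", call. = FALSE)
    return("both")
  }
  pos <- mean(curved > 0)
  if (pos >= threshold) "CCW" else if (1 - pos >= threshold) "CW" else "both"
}

#' Mirror a series through the X = 0 plane
#'
#' Negates every X coordinate. Mirroring flips the sign of every
#' straightness angle and swaps the inside/outside roles of the arms while
#' leaving all body-part angles unchanged; useful for symmetry checks.
#'
#' @param series A [marker_series()].
#' @return The mirrored [marker_series()].
#' @export
mirror_x <- function(series) {
  coords <- series$coords
  coords[, , "X"] <- -coords[, , "X"]
  marker_series(series$trial_id, series$fps, series$frames, coords)
}

#' Extract all features from one trial
#'
#' The full per-trial pipeline: trimming; the two independent frame
#' filters (ankle availability for straightness, arm-artifact rejection
#' for angles); gap-based chunk splitting on each path; step detection on
#' the smoothed inter-foot distance per straightness chunk; signed
#' straightness from step-vector triples with overlap averaging; the
#' 24-angle catalogue on artifact-filtered frames; and aggregation of
#' angle means/SDs by straightness group.
#'
#' @param series A raw (untrimmed) [marker_series()].
#' @param params Parameter list from [feature_params()].
#' @return A list: `features` (aggregated table), `straightness`
#'   (per-frame values), `direction` (trial direction class), `qc` (frame
#'   / chunk / step counts).
#' @export
extract_trial_features <- function(series, params = feature_params()) {
  trimmed <- trim_trial(series, params$trim_seconds)

  # straightness path
  s_mask <- ankle_availability_mask(trimmed)
  s_chunks <- split_chunks(s_mask, params$gap_threshold, params$min_chunk)
  st_list <- list()
  n_steps <- 0L
  n_chunks_used <- 0L
  for (ch in s_chunks) {
    d <- interfoot_distance(ch, trimmed)
    sm <- smooth_distance(d, params$sg_window, params$sg_order)
    steps <- detect_steps(sm, ch, trimmed,
                          min_separation_s = params$min_step_separation_s,
                          min_prominence = params$min_prominence,
                          min_steps = params$min_steps,
                          step_point = params$step_point)
    if (nrow(steps) < params$min_steps) next
    ang <- straightness_angles(steps)
    if (nrow(ang) == 0) next
    st_list[[length(st_list) + 1L]] <- assign_straightness(ang)
    n_steps <- n_steps + nrow(steps)
    n_chunks_used <- n_chunks_used + 1L
  }
  straightness <- if (length(st_list) > 0) {
    do.call(rbind, st_list)
  } else {
    data.frame(frame = integer(0), theta = numeric(0))
  }

  # angle path
  a_mask <- arm_artifact_mask(trimmed, params$sd_multiplier)
  a_chunks <- split_chunks(a_mask, params$gap_threshold, params$min_chunk)
  a_frames <- sort(unique(unlist(lapply(a_chunks, `[[`, "frames"))))
  angles <- if (length(a_frames) > 0) {
    compute_angles(trimmed, a_frames)
  } else {
    matrix(numeric(0), nrow = 0, ncol = 24,
           dimnames = list(NULL, as.character(1:24)))
  }

  features <- aggregate_features(straightness, angles, a_frames,
                                 series$trial_id)
  direction <- if (nrow(straightness) > 0) {
    suppressWarnings(classify_walk_direction(straightness,
                                             params$direction_threshold))
  } else {
    NA_character_
  }

  list(
    features = features,
    straightness = straightness,
    direction = direction,
    qc = list(
      trial_id = series$trial_id,
      n_frames_raw = n_frames(series),
      n_frames_trimmed = n_frames(trimmed),
      n_frames_straightness = length(s_mask$kept),
      n_frames_angles = length(a_mask$kept),
      n_chunks_straightness = length(s_chunks),
      n_chunks_used = n_chunks_used,
      n_chunks_angles = length(a_chunks),
      n_steps = n_steps
    )
  )
}
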