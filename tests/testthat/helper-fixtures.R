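# Shared fixture builders for the test suite.

# A tiny fully-observed series with every marker at fixed positions plus a
# per-frame forward drift; handy for IO round-trips and mask tests.
tiny_series <- function(n = 5, trial_id = "tiny", markers = marker_vocabulary()) {
  coords <- array(NA_real_, dim = c(n, length(markers), 3),
                  dimnames = list(NULL, markers, c("X", "Y", "Z")))
  for (j in seq_along(markers)) {
    coords[, j, "X"] <- seq_len(n) * 0.01 + j
    coords[, j, "Y"] <- 1 + j / 100
    coords[, j, "Z"] <- j / 10
  }
  marker_series(trial_id, 100, seq_len(n) - 1L, coords)
}

# A series holding only the named markers, with coordinates supplied as a
# named list of n x 3 matrices.
series_from_list <- function(xyz, trial_id = "manual", fps = 100) {
  n <- nrow(xyz[[1]])
  coords <- array(NA_real_, dim = c(n, length(xyz), 3),
                  dimnames = list(NULL, names(xyz), c("X", "Y", "Z")))
  for (m in names(xyz)) coords[, m, ] <- xyz[[m]]
  marker_series(trial_id, fps, seq_len(n) - 1L, coords)
}

# Step events laid out on a regular N-gon of circumradius r, traversed CCW
# (dir = +1) or CW (dir = -1); frames spaced evenly.
polygon_steps <- function(n_sides, r = 2, dir = 1, spacing = 50) {
  k <- 0:n_sides
  ang <- dir * 2 * pi * k / n_sides
  data.frame(frame = k * spacing,
             side = rep(c("left", "right"), length.out = n_sides + 1),
             x = r * cos(ang), z = r * sin(ang))
}

# A clean single-emotion walking trial: zero noise, no gaps, no artifacts.
clean_walk <- function(emotion = "Happy", radius = 3.72, duration_s = 150,
                       direction = "CCW", path_kind = "circle", seed = 42,
                       ...) {
  walk_config(path_kind = path_kind, direction = direction, radius = radius,
              noise_sd = 0, gap_rate = 0, artifact_rate = 0,
              duration_s = duration_s, seed = seed, ...)
}

clean_meta <- function(emotion = "Happy", trial_id = "t1",
                       gender = "Male") {
  expected <- c(Happy = "Positive", Sad = "Negative", Neither = "Neutral")
  trial_metadata(trial_id, "s1", expected[[emotion]], emotion, gender)
}

# Radii whose per-step turning angle lands mid-bin at the default cadence
# and step length (turn = step_length / radius in radians).
midbin_radius <- function(turn_deg, step_length = 0.65) {
  step_length * 180 / (pi * turn_deg)
}
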