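#' Trim the start and end of a walking trial
#'
#' Removes `trim_seconds` of frames from each end of the trial (6,000
#' frames at 100 fps with the default 60 s window), discarding the
#' settling-in and wind-down phases.
#'
#' @param series A [marker_series()].
#' @param trim_seconds Seconds to drop from each end (default 60).
#' @return The trimmed [marker_series()].
#' @export
trim_trial <- function(series, trim_seconds = 60) {
  k <- as.integer(round(trim_seconds * series$fps))
  n <- n_frames(series)
  if (n <= 2 * k) {
    stop("trial '", series$trial_id, "' has ", n, " frames; trimming ", k,
         " from each end leaves nothing", call. = FALSE)
  }
  keep <- (k + 1):(n - k)
  marker_series(series$trial_id, series$fps, series$frames[keep],
                series$coords[keep, , , drop = FALSE])
}

#' Frame mask constructor
#'
#' A frame mask records which frames of a (trimmed) trial survive one of
#' the two independent preprocessing paths: `"straightness"` (both ankle
#' markers available) or `"angles"` (no anomalous arm elevation).
#'
#' @param trial_id Trial identifier.
#' @param purpose `"straightness"` or `"angles"`.
#' @param kept Integer frame indices kept.
#' @param domain Integer range (first, last frame) of the trial the mask
#'   was computed over.
#' @return An object of class `frame_mask`.
#' @export
frame_mask <- function(trial_id, purpose = c("straightness", "angles"),
                       kept, domain) {
  purpose <- match.arg(purpose)
  structure(list(trial_id = trial_id, purpose = purpose,
                 kept = as.integer(kept), domain = as.integer(domain)),
            class = "frame_mask")
}

#' Keep frames where both ankle markers are available
#'
#' The walking-straightness path uses the two ankle markers only; any
#' frame missing either marker is excluded from straightness computation.
#'
#' @param series A trimmed [marker_series()].
#' @return A [frame_mask()] with purpose `"straightness"`.
#' @export
ankle_availability_mask <- function(series) {
  ok <- marker_available(series, "LeftAnkleOut") &
    marker_available(series, "RightAnkleOut")
  frame_mask(series$trial_id, "straightness", series$frames[ok],
             range(series$frames))
}

#' Drop frames with anomalous arm elevation
#'
#' For each of the eight arm-related markers (left/right HandOut,
#' WristOut, WristIn, ElbowOut) the mean and SD of its vertical (Y)
#' coordinate are computed once over the whole trimmed trial's available
#' frames. Any frame in which any arm marker's Y lies strictly below
#' mean - `sd_multiplier`*SD or strictly above mean + `sd_multiplier`*SD
#' is removed from the body-part-angle path. This catches non-gait arm
#' movements (watch checks, glasses adjustment, head scratching). Frames
#' where an arm marker is simply missing are not dropped here; missingness
#' is handled per angle during feature extraction.
#'
#' With strict inequalities a constant Y (SD = 0) drops nothing.
#'
#' @param series A trimmed [marker_series()].
#' @param sd_multiplier Threshold in SD units (default 2).
#' @return A [frame_mask()] with purpose `"angles"`.
#' @export
arm_artifact_mask <- function(series, sd_multiplier = 2) {
  drop <- rep(FALSE, n_frames(series))
  for (m in arm_markers()) {
    y <- marker_xyz(series, m)[, "Y"]
    avail <- is.finite(y)
    if (!any(avail)) {
      warning("arm marker '", m, "' absent for entire trial '",
              series$trial_id, "'; skipped by artifact filter",
              call. = FALSE)
      next
    }
    mu <- mean(y[avail])
    sd_y <- stats::sd(y[avail])
    if (!is.finite(sd_y)) sd_y <- 0
    out <- avail & (y < mu - sd_multiplier * sd_y |
                      y > mu + sd_multiplier * sd_y)
    drop <- drop | out
  }
  frame_mask(series$trial_id, "angles", series$frames[!drop],
             range(series$frames))
}

#' Split a masked trial into contiguous walking chunks
#'
#' A run of more than `gap_threshold` consecutive excluded frames starts a
#' new chunk; shorter runs stay inside the chunk as internal gaps. Chunks
#' with fewer than `min_chunk` kept frames are discarded as unusable.
#'
#' The boundary case of a gap of exactly `gap_threshold` frames does not
#' split (the split rule is strictly "more than").
#'
#' @param mask A [frame_mask()].
#' @param gap_threshold Maximum internal gap, frames (default 25).
#' @param min_chunk Minimum kept frames per chunk (default 50).
#' @return A list of chunks; each chunk is a list with `trial_id`,
#'   `purpose` and `frames` (kept frame indices, possibly with internal
#'   gaps).
#' @export
split_chunks <- function(mask, gap_threshold = 25, min_chunk = 50) {
  kept <- sort(mask$kept)
  if (length(kept) == 0) return(list())
  gap_after <- diff(kept) - 1L
  new_chunk <- c(FALSE, gap_after > gap_threshold)
  grp <- cumsum(new_chunk)
  chunks <- split(kept, grp)
  chunks <- chunks[vapply(chunks, length, integer(1)) >= min_chunk]
  unname(lapply(chunks, function(fr) {
    list(trial_id = mask$trial_id, purpose = mask$purpose, frames = fr)
  }))
}
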