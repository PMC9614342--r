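#' Canonical optical marker vocabulary
#'
#' The 37-marker baseline set used for full-body skeleton tracking: five
#' unpaired midline markers (HeadTop, HeadFront, HeadSide, BackTop, Chest)
#' plus sixteen Left/Right marker pairs. Names follow the body-part-angle
#' naming style (e.g. `WaistLeftFront`, `BackLeft`, `LeftThighFront`);
#' alternative spellings seen in marker-set listings resolve through
#' [resolve_marker()].
#'
#' @return Character vector of 37 canonical marker names.
#' @seealso [resolve_marker()], [angle_definitions()]
#' @export
marker_vocabulary <- function() {
  c(
    "HeadTop", "HeadFront", "HeadSide", "BackTop", "Chest",
    "BackLeft", "BackRight",
    "WaistLeftFront", "WaistRightFront",
    "WaistLeftBack", "WaistRightBack",
    "LeftShoulderBack", "RightShoulderBack",
    "LeftShoulderTop", "RightShoulderTop",
    "LeftElbowOut", "RightElbowOut",
    "LeftUpperArmHigh", "RightUpperArmHigh",
    "LeftWristOut", "RightWristOut",
    "LeftWristIn", "RightWristIn",
    "LeftHandOut", "RightHandOut",
    "LeftThighFront", "RightThighFront",
    "LeftKneeOut", "RightKneeOut",
    "LeftShin", "RightShin",
    "LeftAnkleOut", "RightAnkleOut",
    "LeftToeOut", "RightToeOut",
    "LeftToeIn", "RightToeIn"
  )
}

# Alias map: every non-canonical spelling in use -> canonical name.
# Covers the thigh-marker spelling discrepancy ("ThightFront" in the marker
# listing vs "Thigh" in the angle catalogue) and side-prefix variants of the
# waist/back markers.
.marker_aliases <- function() {
  c(
    "LeftThigh"        = "LeftThighFront",
    "RightThigh"       = "RightThighFront",
    "LeftThightFront"  = "LeftThighFront",
    "RightThightFront" = "RightThighFront",
    "ThightFrontLeft"  = "LeftThighFront",
    "ThightFrontRight" = "RightThighFront",
    "LeftBack"         = "BackLeft",
    "RightBack"        = "BackRight",
    "LeftWaistFront"   = "WaistLeftFront",
    "RightWaistFront"  = "WaistRightFront",
    "LeftWaistBack"    = "WaistLeftBack",
    "RightWaistBack"   = "WaistRightBack"
  )
}

#' Resolve a marker name or alias to its canonical form
#'
#' @param name Character vector of marker names or aliases.
#' @param error Logical; if `TRUE` (default) unknown names raise an error,
#'   otherwise they return `NA`.
#' @return Character vector of canonical names.
#' @export
resolve_marker <- function(name, error = TRUE) {
  vocab <- marker_vocabulary()
  alias <- .marker_aliases()
  out <- ifelse(name %in% vocab, name,
                unname(alias[match(name, names(alias))]))
  if (error && anyNA(out)) {
    stop("unknown marker name(s): ",
         paste(unique(name[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' The catalogue of 24 body-part angles
#'
#' Each angle is defined by a marker triple: the angle at the `vertex`
#' marker between the vectors pointing to `terminal1` and `terminal2`,
#' measured in 3-D and reported in degrees. Indices 19 and 20 are the left
#' and right shoulder-arm angles whose within-bin standard deviation is
#' interpreted as arm-swing magnitude.
#'
#' @return A data.frame with columns `index`, `terminal1`, `vertex`,
#'   `terminal2` (24 rows, canonical marker names).
#' @export
angle_definitions <- function() {
  raw <- list(
    list(1L,  "LeftAnkleOut",      "LeftKneeOut",       "WaistLeftFront"),
    list(2L,  "RightAnkleOut",     "RightKneeOut",      "WaistRightFront"),
    list(3L,  "LeftShin",          "LeftKneeOut",       "LeftThigh"),
    list(4L,  "RightShin",         "RightKneeOut",      "RightThigh"),
    list(5L,  "LeftKneeOut",       "LeftThigh",         "WaistLeftFront"),
    list(6L,  "RightKneeOut",      "RightThigh",        "WaistRightFront"),
    list(7L,  "LeftThigh",         "WaistLeftFront",    "Chest"),
    list(8L,  "RightThigh",        "WaistRightFront",   "Chest"),
    list(9L,  "WaistLeftFront",    "Chest",             "LeftShoulderTop"),
    list(10L, "WaistRightFront",   "Chest",             "RightShoulderTop"),
    list(11L, "LeftKneeOut",       "WaistLeftBack",     "BackLeft"),
    list(12L, "RightKneeOut",      "WaistRightBack",    "BackRight"),
    list(13L, "WaistLeftBack",     "BackLeft",          "LeftShoulderBack"),
    list(14L, "WaistRightBack",    "BackRight",         "RightShoulderBack"),
    list(15L, "LeftShoulderBack",  "BackTop",           "HeadTop"),
    list(16L, "RightShoulderBack", "BackTop",           "HeadTop"),
    list(17L, "BackLeft",          "BackTop",           "HeadTop"),
    list(18L, "BackRight",         "BackTop",           "HeadTop"),
    list(19L, "BackLeft",          "LeftShoulderBack",  "LeftUpperArmHigh"),
    list(20L, "BackRight",         "RightShoulderBack", "RightUpperArmHigh"),
    list(21L, "BackTop",           "LeftShoulderBack",  "LeftUpperArmHigh"),
    list(22L, "BackTop",           "RightShoulderBack", "RightUpperArmHigh"),
    list(23L, "LeftUpperArmHigh",  "LeftElbowOut",      "LeftWristOut"),
    list(24L, "RightUpperArmHigh", "RightElbowOut",     "RightWristOut")
  )
  df <- data.frame(
    index     = vapply(raw, function(r) r[[1]], integer(1)),
    terminal1 = resolve_marker(vapply(raw, function(r) r[[2]], character(1))),
    vertex    = resolve_marker(vapply(raw, function(r) r[[3]], character(1))),
    terminal2 = resolve_marker(vapply(raw, function(r) r[[4]], character(1))),
    stringsAsFactors = FALSE
  )
  df
}

#' The eight arm-related markers used by the arm-artifact frame filter
#' @return Character vector of canonical names.
#' @export
arm_markers <- function() {
  c("LeftHandOut", "RightHandOut", "LeftWristOut", "RightWristOut",
    "LeftWristIn", "RightWristIn", "LeftElbowOut", "RightElbowOut")
}

#' The seven straightness groups
#'
#' Half-open 10-degree bins of the signed walking-straightness angle,
#' spanning -35 to +35 degrees. Negative angles are clockwise turning,
#' positive counter-clockwise; values outside \[-35, 35) are unbinned.
#'
#' @return A data.frame with columns `label`, `lo`, `hi`, `magnitude`
#'   (0, 10, 20 or 30) and `direction` ("CW", "straight", "CCW").
#' @export
straightness_groups <- function() {
  lo <- c(-35, -25, -15, -5, 5, 15, 25)
  hi <- lo + 10
  data.frame(
    label     = sprintf("%d to %d", lo, hi),
    lo        = lo,
    hi        = hi,
    magnitude = c(30, 20, 10, 0, 10, 20, 30),
    direction = c("CW", "CW", "CW", "straight", "CCW", "CCW", "CCW"),
    stringsAsFactors = FALSE
  )
}
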