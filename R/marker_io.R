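#' Construct a marker frame series
#'
#' A `marker_series` holds frame-indexed 3-D positions of named optical
#' markers for one walking trial. Coordinates are metric: X and Z span the
#' horizontal (top-view) ground plane, Y is vertical. A missing marker
#' observation is stored as `NA` in all three coordinates.
#'
#' @param trial_id Trial identifier string.
#' @param fps Frames per second (default 100).
#' @param frames Strictly increasing integer frame indices (0-based).
#' @param coords Numeric array `length(frames) x n_markers x 3` with
#'   dimnames `list(NULL, marker_names, c("X","Y","Z"))`.
#' @return An object of class `marker_series`.
#' @export
marker_series <- function(trial_id, fps = 100, frames, coords) {
  frames <- as.integer(frames)
  stopifnot(fps > 0, length(frames) == dim(coords)[1], dim(coords)[3] == 3)
  if (length(frames) > 1 && any(diff(frames) <= 0)) {
    stop("frame indices must be strictly increasing", call. = FALSE)
  }
  if (is.null(dimnames(coords)[[2]])) {
    stop("coords must carry marker names in dimnames", call. = FALSE)
  }
  dimnames(coords)[[3]] <- c("X", "Y", "Z")
  structure(
    list(trial_id = trial_id, fps = fps, frames = frames, coords = coords),
    class = "marker_series"
  )
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf(
    "<marker_series> trial '%s': %d frames @ %g fps, %d markers, %.1f%% missing\n",
    x$trial_id, length(x$frames), x$fps, dim(x$coords)[2],
    100 * mean(is.na(x$coords[, , 1]))
  ))
  invisible(x)
}

#' Number of frames in a series
#' @param series A `marker_series`.
#' @return Integer frame count.
#' @export
n_frames <- function(series) length(series$frames)

#' Extract one marker's coordinates
#'
#' @param series A `marker_series`.
#' @param name Marker name or alias.
#' @return Numeric matrix `n_frames x 3` (X, Y, Z); rows of `NA` where the
#'   marker was not observed.
#' @export
marker_xyz <- function(series, name) {
  name <- resolve_marker(name)
  if (!name %in% dimnames(series$coords)[[2]]) {
    stop("marker '", name, "' not present in series", call. = FALSE)
  }
  series$coords[, name, , drop = TRUE]
}

#' Which frames have a marker fully observed
#' @param series A `marker_series`.
#' @param name Marker name or alias.
#' @return Logical vector over the series' frames.
#' @export
marker_available <- function(series, name) {
  xyz <- marker_xyz(series, name)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  rowSums(is.finite(xyz)) == 3L
}

#' Subset a series to a set of frame indices
#' @param series A `marker_series`.
#' @param frames Frame indices (values of `series$frames`) to keep.
#' @return A `marker_series` restricted to those frames.
#' @export
subset_frames <- function(series, frames) {
  keep <- series$frames %in% frames
  marker_series(series$trial_id, series$fps,
                series$frames[keep],
                series$coords[keep, , , drop = FALSE])
}

# ---------------------------------------------------------------------------
# Wide-CSV marker table IO.
# Header: frame,<Marker>.X,<Marker>.Y,<Marker>.Z,...  Empty cell = missing.

#' Read a marker trajectory table
#'
#' Reads the wide CSV dialect `frame,<Marker>.X,<Marker>.Y,<Marker>.Z,...`.
#' Empty cells become missing marker entries. Column marker names are
#' resolved through the alias map; unknown markers are rejected.
#'
#' @param path Path to a CSV file.
#' @param trial_id Trial identifier; defaults to the file name without
#'   extension.
#' @param fps Frames per second recorded in the file (default 100).
#' @return A [marker_series()].
#' @export
read_marker_table <- function(path, trial_id = NULL,  fps = 100) {
  if (is.null(trial_id)) {
    trial_id <- sub("\\.[^.]+$", "", basename(path))
  }
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = "character", na.strings = "")
  cols <- names(dt)
  if (length(cols) == 0 || cols[1] != "frame") {
    stop("malformed header in '", path, "': first column must be 'frame'",
         call. = FALSE)
  }
  coord_cols <- cols[-1]
  m <- regmatches(coord_cols, regexec("^(.*)\\.([XYZ])$", coord_cols))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    stop("malformed header: column(s) ",
         paste(coord_cols[bad], collapse = ", "),
         " are not of the form <Marker>.<X|Y|Z>", call. = FALSE)
  }
  raw_names <- vapply(m, `[`, character(1), 2)
  axes      <- vapply(m, `[`, character(1), 3)
  canon <- resolve_marker(unique(raw_names))
  names(canon) <- unique(raw_names)
  # every marker must come as a complete X/Y/Z triple
  for (rn in unique(raw_names)) {
    have <- sort(axes[raw_names == rn])
    if (!identical(have, c("X", "Y", "Z"))) {
      stop("marker '", rn, "' has incomplete coordinate columns (",
           paste(have, collapse = ","), ")", call. = FALSE)
    }
  }
  frames_chr <- dt[["frame"]]
  frames <- suppressWarnings(as.integer(frames_chr))
  if (anyNA(frames)) {
    stop("non-integer frame index at row ",
         which(is.na(frames))[1], call. = FALSE)
  }
  if (anyDuplicated(frames)) {
    stop("duplicate frame index ", frames[anyDuplicated(frames)],
         call. = FALSE)
  }
  markers <- unname(canon[unique(raw_names)])
  coords <- array(NA_real_, dim = c(nrow(dt), length(markers), 3),
                  dimnames = list(NULL, markers, c("X", "Y", "Z")))
  for (j in seq_along(coord_cols)) {
    v_chr <- dt[[coord_cols[j]]]
    v <- suppressWarnings(as.numeric(v_chr))
    bad_row <- which(is.na(v) & !is.na(v_chr))
    if (length(bad_row) > 0) {
      stop("non-numeric coordinate in column '", coord_cols[j],
           "' at row ", bad_row[1], call. = FALSE)
    }
    coords[, canon[raw_names[j]], axes[j]] <- v
  }
  # a marker entry is all-or-nothing: partial triples count as missing
  partial <- is.na(coords[, , 1, drop = FALSE]) |
             is.na(coords[, , 2, drop = FALSE]) |
             is.na(coords[, , 3, drop = FALSE])
  for (k in 1:3) coords[, , k][partial[, , 1]] <- NA_real_
  ord <- order(frames)
  marker_series(trial_id, fps, frames[ord], coords[ord, , , drop = FALSE])
}

#' Write a marker trajectory table
#'
#' Inverse of [read_marker_table()]: writes the wide CSV dialect with empty
#' cells for missing entries and fixed 9-decimal formatting, so output is
#' byte-stable and round-trips to within 1e-9 m.
#'
#' @param series A [marker_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(series, path) {
  markers <- dimnames(series$coords)[[2]]
  cols <- c("frame", as.vector(t(outer(markers, c("X", "Y", "Z"),
                                       function(m, a) paste0(m, ".", a)))))
  n <- length(series$frames)
  mat <- matrix("", nrow = n, ncol = length(cols))
  mat[, 1] <- as.character(series$frames)
  ci <- 2L
  for (m in markers) {
    for (a in c("X", "Y", "Z")) {
      v <- series$coords[, m, a]
      s <- sprintf("%.9f", v)
      s[!is.finite(v)] <- ""
      mat[, ci] <- s
      ci <- ci + 1L
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  if (n > 0) writeLines(apply(mat, 1, paste, collapse = ","), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Trial metadata IO.

#' Construct a trial metadata table
#'
#' @param trial_id,subject_id Character vectors.
#' @param expected_emotion One of "Positive", "Negative", "Neutral" (the
#'   stimulus valence).
#' @param reported_emotion One of "Happy", "Sad", "Neither" (self-report).
#' @param gender "Male" or "Female".
#' @param corrupted Logical flag; corrupted trials are excluded from
#'   analysis.
#' @return A data.frame with one row per trial.
#' @export
trial_metadata <- function(trial_id, subject_id, expected_emotion,
                           reported_emotion, gender,
                           corrupted = FALSE) {
  stopifnot(all(expected_emotion %in% c("Positive", "Negative", "Neutral")),
            all(reported_emotion %in% c("Happy", "Sad", "Neither")),
            all(gender %in% c("Male", "Female")))
  data.frame(trial_id = trial_id, subject_id = subject_id,
             expected_emotion = expected_emotion,
             reported_emotion = reported_emotion,
             gender = gender, corrupted = corrupted,
             stringsAsFactors = FALSE)
}

#' Read / write trial metadata CSV
#'
#' Columns: `trial_id,subject_id,expected_emotion,reported_emotion,gender,
#' corrupted`.
#'
#' @param path File path.
#' @return `read_trial_metadata`: a metadata data.frame.
#' @export
read_trial_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "subject_id", "expected_emotion",
            "reported_emotion", "gender", "corrupted")
  if (!all(need %in% names(df))) {
    stop("metadata file missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  df$corrupted <- as.logical(df$corrupted)
  trial_metadata(df$trial_id, df$subject_id, df$expected_emotion,
                 df$reported_emotion, df$gender, df$corrupted)
}

#' @rdname read_trial_metadata
#' @param meta Metadata data.frame.
#' @export
write_trial_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
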