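AU_LABELS <- c("AU01", "AU02", "AU04", "AU15", "AU25", "AU26", "AU45")

frame_feature_cols <- function() {
  c("frame", "confidence", "success",
    "gaze_angle_x", "gaze_angle_y",
    "pose_Tx", "pose_Ty", "pose_Tz",
    "pose_Rx", "pose_Ry", "pose_Rz",
    paste0(AU_LABELS, "_r"))
}

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
  tab <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal"),
    error = function(e) abort(sprintf("Could not parse %s file %s: %s",
                                      what, path, conditionMessage(e)))
  )
  names(tab) <- trimws(names(tab))
  if (nrow(tab) == 0) abort(sprintf("%s file is empty: %s", what, path))
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(sprintf("%s file %s is missing required column(s): %s",
                  what, path, paste(missing, collapse = ", ")))
  }
  tab
}

#' Read a per-frame facial-feature table
#'
#' Parses the comma-separated per-frame output of a webcam facial-analysis
#' pipeline (OpenFace 2.0 dialect): detection confidence and success flag,
#' gaze angles, head pose translation (mm) and rotation, and facial action
#' unit (AU) intensities. Extra columns are ignored; whitespace after commas
#' is tolerated.
#'
#' Frames failing the detection-success flag or falling below
#' `confidence_floor` are kept but marked `valid = FALSE`, and are excluded
#' from all downstream biomarker computations. Gaze angles and pose
#' rotations are emitted in radians by the upstream tool and converted to
#' degrees on read (disable with `angles_in_radians = FALSE` for tables
#' already in degrees). Negative AU intensities (small estimation artefacts)
#' are clamped to zero. If no `timestamp` column is present, timestamps are
#' reconstructed as `frame / frame_rate`.
#'
#' @param path CSV file path.
#' @param confidence_floor Minimum detection confidence for a frame to count
#'   as valid (default 0.75).
#' @param angles_in_radians Are gaze angles and pose rotations stored in
#'   radians (default `TRUE`)?
#' @param frame_rate Nominal frame rate in Hz, used only to reconstruct
#'   missing timestamps (default 5).
#' @return A tibble of frame records: `frame`, `t` (s), `valid`,
#'   `confidence`, `gaze_x`, `gaze_y` (deg), `head_x`, `head_y`, `head_z`
#'   (mm), `head_pitch`, `head_yaw`, `head_roll` (deg), and `au01` ...
#'   `au45` intensities (arbitrary units, >= 0).
#' @export
read_frame_table <- function(path, confidence_floor = 0.75,
                             angles_in_radians = TRUE, frame_rate = 5) {
  tab <- read_checked_csv(path, frame_feature_cols(), "Frame-feature")
  ang <- if (angles_in_radians) 180 / pi else 1
  t <- if ("timestamp" %in% names(tab)) as.numeric(tab$timestamp) else {
    as.numeric(tab$frame) / frame_rate
  }
  if (is.unsorted(t, na.rm = TRUE)) {
    abort("Frame timestamps must be non-decreasing within a session.")
  }
  out <- tibble::tibble(
    frame = as.integer(tab$frame),
    t = t,
    confidence = as.numeric(tab$confidence),
    valid = as.numeric(tab$success) == 1 &
      as.numeric(tab$confidence) >= confidence_floor,
    gaze_x = as.numeric(tab$gaze_angle_x) * ang,
    gaze_y = as.numeric(tab$gaze_angle_y) * ang,
    head_x = as.numeric(tab$pose_Tx),
    head_y = as.numeric(tab$pose_Ty),
    head_z = as.numeric(tab$pose_Tz),
    head_pitch = as.numeric(tab$pose_Rx) * ang,
    head_yaw = as.numeric(tab$pose_Ry) * ang,
    head_roll = as.numeric(tab$pose_Rz) * ang
  )
  for (au in AU_LABELS) {
    out[[tolower(au)]] <- pmax(as.numeric(tab[[paste0(au, "_r")]]), 0)
  }
  out
}

#' Read a trial log
#'
#' Columns: `trial`, `location_id`, `stimulus_db`, `onset_s`, `responded`
#' (0/1), `latency_s` (empty when there was no response). Records are
#' returned sorted by onset time. Latency must be present exactly when a
#' response was made, and positive.
#'
#' @param path CSV file path.
#' @return A tibble of trial records sorted by `onset_s`, with `responded`
#'   logical and `latency_s` `NA` for missed trials.
#' @export
read_trial_log <- function(path) {
  req <- c("trial", "location_id", "stimulus_db", "onset_s", "responded", "latency_s")
  tab <- read_checked_csv(path, req, "Trial-log")
  out <- tibble::tibble(
    trial = as.integer(tab$trial),
    location_id = as.integer(tab$location_id),
    stimulus_db = as.numeric(tab$stimulus_db),
    onset_s = as.numeric(tab$onset_s),
    responded = as.numeric(tab$responded) == 1,
    latency_s = suppressWarnings(as.numeric(tab$latency_s))
  )
  validate_trials(out)
  dplyr::arrange(out, .data$onset_s)
}

validate_trials <- function(trials) {
  bad <- trials$responded & is.na(trials$latency_s)
  if (any(bad)) {
    abort(sprintf("Trial(s) %s responded but have no latency.",
                  paste(trials$trial[bad], collapse = ", ")))
  }
  bad <- !trials$responded & !is.na(trials$latency_s)
  if (any(bad)) {
    abort(sprintf("Trial(s) %s carry a latency without a response.",
                  paste(trials$trial[bad], collapse = ", ")))
  }
  bad <- !is.na(trials$latency_s) & trials$latency_s <= 0
  if (any(bad)) {
    abort(sprintf("Trial(s) %s have non-positive latency.",
                  paste(trials$trial[bad], collapse = ", ")))
  }
  if (any(!is.finite(trials$stimulus_db))) {
    abort("All stimulus levels must be finite dB values.")
  }
  invisible(trials)
}

#' Read a threshold grid
#'
#' Columns: `location_id`, `x_deg`, `y_deg`, `dls_db`. Exactly 24 locations
#' (the central 4 x 6 portion of the 24-2 grid) are required.
#'
#' @param path CSV file path.
#' @return A 24-row tibble.
#' @export
read_threshold_grid <- function(path) {
  req <- c("location_id", "x_deg", "y_deg", "dls_db")
  tab <- read_checked_csv(path, req, "Threshold-grid")
  out <- tibble::tibble(
    location_id = as.integer(tab$location_id),
    x_deg = as.numeric(tab$x_deg),
    y_deg = as.numeric(tab$y_deg),
    dls_db = as.numeric(tab$dls_db)
  )
  validate_threshold_grid(out)
  out
}

validate_threshold_grid <- function(grid) {
  if (nrow(grid) != 24 || anyDuplicated(grid$location_id)) {
    abort(sprintf("Threshold grid must have exactly 24 unique locations; got %d.",
                  nrow(grid)))
  }
  invisible(grid)
}

#' Write session components in the same CSV dialects the readers accept
#'
#' `write_frame_table()` converts degrees back to radians (when
#' `angles_in_radians = TRUE`) so a written table round-trips through
#' [read_frame_table()].
#'
#' @param frames,trials,grid Tibbles as produced by the readers or the
#'   synthetic generator.
#' @param path Output CSV path.
#' @param angles_in_radians Write gaze/rotation columns in radians
#'   (default `TRUE`, matching the upstream dialect).
#' @return The path, invisibly.
#' @export
write_frame_table <- function(frames, path, angles_in_radians = TRUE) {
  ang <- if (angles_in_radians) pi / 180 else 1
  out <- tibble::tibble(
    frame = frames$frame,
    timestamp = frames$t,
    confidence = frames$confidence,
    success = as.integer(frames$valid),
    gaze_angle_x = frames$gaze_x * ang,
    gaze_angle_y = frames$gaze_y * ang,
    pose_Tx = frames$head_x, pose_Ty = frames$head_y, pose_Tz = frames$head_z,
    pose_Rx = frames$head_pitch * ang,
    pose_Ry = frames$head_yaw * ang,
    pose_Rz = frames$head_roll * ang
  )
  for (au in AU_LABELS) out[[paste0(au, "_r")]] <- frames[[tolower(au)]]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_frame_table
#' @export
write_trial_log <- function(trials, path) {
  out <- dplyr::mutate(trials, responded = as.integer(.data$responded))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_frame_table
#' @export
write_threshold_grid <- function(grid, path) {
  readr::write_csv(grid, path, progress = FALSE)
  invisible(path)
}
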