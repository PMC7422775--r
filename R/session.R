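#' Assemble a validated visual field session
#'
#' Bundles one assessment's frame stream, trial log and final threshold grid
#' into a `vf_session` object, enforcing the cross-component invariants:
#' every trial onset must fall within the frame stream's time span (with a
#' tolerance of one frame interval) and the threshold grid must cover all 24
#' locations.
#'
#' @param frames Frame tibble from [read_frame_table()] (or the generator).
#' @param trials Trial tibble from [read_trial_log()].
#' @param thresholds 24-row threshold grid from [read_threshold_grid()].
#' @param subject_id,eye Identification labels.
#' @param frame_rate Nominal frame rate in Hz (> 0), default 5.
#' @param quiet Suppress the assembly summary message.
#' @return An object of class `vf_session`.
#' @export
vf_session <- function(frames, trials, thresholds, subject_id = "S01",
                       eye = "OD", frame_rate = 5, quiet = FALSE) {
  if (!(frame_rate > 0)) abort("frame_rate must be > 0 Hz.")
  validate_threshold_grid(thresholds)
  validate_trials(trials)
  if (nrow(frames) > 0 && is.unsorted(frames$t, na.rm = TRUE)) {
    abort("Frame timestamps must be non-decreasing.")
  }
  if (nrow(frames) > 0 && nrow(trials) > 0) {
    tol <- 1 / frame_rate
    span <- range(frames$t)
    out_of_span <- trials$onset_s < span[1] - tol | trials$onset_s > span[2] + tol
    if (any(out_of_span)) {
      abort(sprintf(
        "Trial(s) %s fall outside the frame stream's time span [%.1f, %.1f] s.",
        paste(trials$trial[out_of_span], collapse = ", "), span[1], span[2]
      ))
    }
  }
  s <- structure(
    list(subject_id = subject_id, eye = eye, frame_rate = frame_rate,
         frames = frames, trials = dplyr::arrange(trials, .data$onset_s),
         thresholds = thresholds),
    class = "vf_session"
  )
  if (!quiet) {
    inform(sprintf(
      "Session %s/%s: %d frames (%.1f%% valid), %d trials, 24 thresholds.",
      subject_id, eye, nrow(frames),
      if (nrow(frames) > 0) 100 * mean(frames$valid) else NA_real_,
      nrow(trials)
    ))
  }
  s
}

#' @export
print.vf_session <- function(x, ...) {
  cat(sprintf(
    "<vf_session> %s (%s): %d frames @ %g Hz, %d trials, MS %.1f dB\n",
    x$subject_id, x$eye, nrow(x$frames), x$frame_rate, nrow(x$trials),
    tryCatch(mean_sensitivity(x$thresholds), error = function(e) NA_real_)
  ))
  invisible(x)
}

#' Write or read a whole session as a directory of CSV files
#'
#' A session directory holds `frames.csv` (facial-feature dialect),
#' `trials.csv`, `thresholds.csv` and `session.json` (labels and frame
#' rate). Written sessions round-trip through [read_session()].
#'
#' @param session A [vf_session()].
#' @param dir Directory path (created if needed).
#' @param confidence_floor,quiet Passed through to the readers/constructor.
#' @return `write_session()` the directory path invisibly; `read_session()`
#'   a `vf_session`.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "vf_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_frame_table(session$frames, file.path(dir, "frames.csv"))
  write_trial_log(session$trials, file.path(dir, "trials.csv"))
  write_threshold_grid(session$thresholds, file.path(dir, "thresholds.csv"))
  jsonlite::write_json(
    list(subject_id = session$subject_id, eye = session$eye,
         frame_rate = session$frame_rate),
    file.path(dir, "session.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir, confidence_floor = 0.75, quiet = TRUE) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"), simplifyVector = TRUE)
  frames <- read_frame_table(file.path(dir, "frames.csv"),
                             confidence_floor = confidence_floor,
                             frame_rate = meta$frame_rate)
  vf_session(
    frames = frames,
    trials = read_trial_log(file.path(dir, "trials.csv")),
    thresholds = read_threshold_grid(file.path(dir, "thresholds.csv")),
    subject_id = meta$subject_id, eye = meta$eye,
    frame_rate = meta$frame_rate, quiet = quiet
  )
}
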