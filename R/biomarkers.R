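biomarker_names <- function() {
  c("gaze_variability", "head_location_variability", "head_rotation_variability",
    "mean_sadness", "mean_surprise", "blink_rate", "mean_response_latency")
}

video_biomarker_names <- function() setdiff(biomarker_names(), "mean_response_latency")

valid_frames <- function(frames) dplyr::filter(frames, .data$valid)

frames_of <- function(x) {
  if (inherits(x, "vf_session")) x$frames else x
}

#' Session-level compliance biomarkers
#'
#' The three dispersion biomarkers apply the robust Sn statistic
#' ([sn_dispersion()]) to the valid frames' gaze coordinates (degrees), head
#' location (mm) and head rotation (degrees) respectively. Each returns
#' `NA_real_` when fewer than two valid frames are available.
#'
#' @param x A `vf_session` or a frame tibble.
#' @return A scalar (degrees, mm, or degrees respectively) or `NA_real_`.
#' @export
gaze_variability <- function(x) {
  f <- valid_frames(frames_of(x))
  if (nrow(f) < 2) return(NA_real_)
  sn_dispersion(cbind(f$gaze_x, f$gaze_y))
}

#' @rdname gaze_variability
#' @export
head_location_variability <- function(x) {
  f <- valid_frames(frames_of(x))
  if (nrow(f) < 2) return(NA_real_)
  sn_dispersion(cbind(f$head_x, f$head_y, f$head_z))
}

#' @rdname gaze_variability
#' @export
head_rotation_variability <- function(x) {
  f <- valid_frames(frames_of(x))
  if (nrow(f) < 2) return(NA_real_)
  sn_dispersion(cbind(f$head_yaw, f$head_pitch, f$head_roll))
}

#' Mean summed action-unit intensity over valid frames
#'
#' Facial expressions are summarised by summing the intensities of the
#' action units (AUs) that compose them on each valid frame, then averaging
#' across frames. Sadness uses AU4 (brow lowerer) + AU15 (lip corner
#' depressor); surprise uses AU1 + AU2 (brow raisers) + AU25 (lips part) +
#' AU26 (jaw drop); blink uses AU45 alone.
#'
#' @param frames A frame tibble (or `vf_session`).
#' @param au_labels Character AU labels, e.g. `c("AU04", "AU15")`.
#' @param presence Treat AUs as binary present/absent (intensity > 0)
#'   instead of graded intensity. Default `FALSE` (intensity).
#' @return Mean per-frame intensity sum (arbitrary units), or `NA_real_`
#'   with no valid frames.
#' @export
mean_au_sum <- function(frames, au_labels, presence = FALSE) {
  f <- valid_frames(frames_of(frames))
  if (nrow(f) == 0) return(NA_real_)
  cols <- tolower(au_labels)
  missing <- setdiff(cols, names(f))
  if (length(missing) > 0) {
    abort(sprintf("Frame table lacks AU column(s): %s",
                  paste(toupper(missing), collapse = ", ")))
  }
  m <- as.matrix(f[cols])
  if (presence) m <- (m > 0) * 1
  mean(rowSums(m))
}

#' @rdname mean_au_sum
#' @export
mean_sadness <- function(frames, presence = FALSE) {
  mean_au_sum(frames, c("AU04", "AU15"), presence)
}

#' @rdname mean_au_sum
#' @export
mean_surprise <- function(frames, presence = FALSE) {
  mean_au_sum(frames, c("AU01", "AU02", "AU25", "AU26"), presence)
}

#' @rdname mean_au_sum
#' @export
blink_rate <- function(frames, presence = FALSE) {
  mean_au_sum(frames, "AU45", presence)
}

#' Mean response latency
#'
#' Arithmetic mean of the stimulus-onset-to-button-press latencies over the
#' trials where a response was made; missed trials contribute to neither
#' numerator nor denominator.
#'
#' @param trials A trial tibble (or `vf_session`).
#' @return Seconds, or `NA_real_` if no trial was responded to.
#' @export
mean_response_latency <- function(trials) {
  if (inherits(trials, "vf_session")) trials <- trials$trials
  lat <- trials$latency_s[trials$responded]
  if (length(lat) == 0 || all(is.na(lat))) return(NA_real_)
  mean(lat, na.rm = TRUE)
}

#' All seven compliance biomarkers for a session
#'
#' @param session A [vf_session()].
#' @return A one-row tibble: `subject_id`, `eye`, then the seven biomarkers
#'   (gaze/head dispersions, mean sadness, mean surprise, blink rate, mean
#'   response latency). Fields are `NA` where the session carries too little
#'   data.
#' @export
session_biomarkers <- function(session) {
  stopifnot(inherits(session, "vf_session"))
  tibble::tibble(
    subject_id = session$subject_id,
    eye = session$eye,
    gaze_variability = gaze_variability(session),
    head_location_variability = head_location_variability(session),
    head_rotation_variability = head_rotation_variability(session),
    mean_sadness = mean_sadness(session$frames),
    mean_surprise = mean_surprise(session$frames),
    blink_rate = blink_rate(session$frames),
    mean_response_latency = mean_response_latency(session)
  )
}

#' Per-trial windowed biomarkers
#'
#' Recomputes the six video biomarkers for each requested trial using only
#' the frames from that trial and the `window_frames` frames (4 s at 5 Hz by
#' default) directly preceding stimulus onset — the information that would
#' be available in real time when deciding how much to trust the response.
#' Response latency is excluded by construction (it is undefined for missed
#' trials and so carries no information about them).
#'
#' A trial's window is `[onset - window_frames / frame_rate, onset + dur]`
#' where `dur` is the response latency when the trial was responded to and
#' `trial_duration_s` otherwise. Windows are truncated at the session start.
#' Dispersion fields are `NA` when fewer than two valid frames fall in the
#' window.
#'
#' @param session A [vf_session()].
#' @param trials Integer trial ids to window (default: all trials).
#' @param window_frames Number of preceding frames (default 20).
#' @param trial_duration_s Nominal trial duration used for missed trials
#'   (default 1.5 s).
#' @return A tibble with one row per trial: `trial`, `n_window_frames`, and
#'   the six video biomarkers.
#' @export
windowed_biomarkers <- function(session, trials = NULL, window_frames = 20,
                                trial_duration_s = 1.5) {
  stopifnot(inherits(session, "vf_session"))
  tl <- session$trials
  if (!is.null(trials)) {
    if (!all(trials %in% tl$trial)) {
      abort("Some requested trials do not belong to this session.")
    }
    tl <- dplyr::filter(tl, .data$trial %in% !!trials)
  }
  frames <- session$frames
  pre <- window_frames / session$frame_rate
  purrr::pmap_dfr(
    list(tl$trial, tl$onset_s, tl$responded, tl$latency_s),
    function(trial, onset, responded, latency) {
      dur <- if (isTRUE(responded) && is.finite(latency)) latency else trial_duration_s
      w <- dplyr::filter(frames, .data$t >= onset - pre, .data$t <= onset + dur)
      tibble::tibble(
        trial = trial,
        n_window_frames = nrow(w),
        gaze_variability = gaze_variability(w),
        head_location_variability = head_location_variability(w),
        head_rotation_variability = head_rotation_variability(w),
        mean_sadness = mean_sadness(w),
        mean_surprise = mean_surprise(w),
        blink_rate = blink_rate(w)
      )
    }
  )
}
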