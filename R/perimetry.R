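#' Convert differential light sensitivity between cd/m2 and dB
#'
#' Perimetric decibels are an attenuation scale referenced to a maximum
#' stimulus luminance: `dB = 10 * log10(3183.1 / DLS)`, with DLS in cd/m2.
#' Higher dB means a dimmer stimulus was detectable, i.e. better
#' sensitivity. The two functions are exact inverses.
#'
#' @param dls Differential light sensitivity in cd/m2; must be positive.
#' @param db Sensitivity in dB.
#' @return Numeric vector of the converted values.
#' @examples
#' dls_to_db(3183.1)  # 0 dB
#' dls_to_db(318.31)  # 10 dB
#' db_to_dls(dls_to_db(250))  # 250
#' @export
dls_to_db <- function(dls) {
  if (any(!is.finite(dls)) || any(dls <= 0)) {
    abort("DLS must be finite and > 0 cd/m2 to express in dB.")
  }
  10 * log10(3183.1 / dls)
}

#' @rdname dls_to_db
#' @export
db_to_dls <- function(db) {
  if (any(!is.finite(db))) abort("dB values must be finite.")
  3183.1 / 10^(db / 10)
}

#' Central 24 locations of the 24-2 perimetric grid
#'
#' A 4 x 6 grid spanning +/-15 degrees horizontally and +/-9 degrees
#' vertically (3-degree offset lattice with 6-degree spacing), the central
#' portion of the standard 24-2 test pattern.
#'
#' @return A tibble with columns `location_id`, `x_deg`, `y_deg` (24 rows).
#' @export
grid_24_2_central <- function() {
  g <- tidyr::expand_grid(
    y_deg = c(9, 3, -3, -9),
    x_deg = c(-15, -9, -3, 3, 9, 15)
  )
  tibble::tibble(location_id = seq_len(nrow(g)), x_deg = g$x_deg, y_deg = g$y_deg)
}

#' Mean sensitivity of a threshold grid
#'
#' The summary score of a visual field assessment: the arithmetic mean of
#' the 24 pointwise DLS estimates in dB.
#'
#' @param thresholds A threshold grid tibble with a `dls_db` column (one row
#'   per location, 24 rows), or a bare numeric vector of 24 dB values.
#' @return Mean sensitivity in dB.
#' @export
mean_sensitivity <- function(thresholds) {
  db <- if (is.data.frame(thresholds)) thresholds$dls_db else as.numeric(thresholds)
  if (is.null(db)) abort("Threshold grid must carry a `dls_db` column.")
  if (length(db) != 24 || anyNA(db)) {
    abort(sprintf(
      "Mean sensitivity needs all 24 locations in dB; got %d non-missing of %d.",
      sum(!is.na(db)), length(db)
    ))
  }
  mean(db)
}

#' Test-retest measurement error
#'
#' Absolute difference in mean sensitivity between two assessments of the
#' same eye, in dB.
#'
#' @param ms1,ms2 Mean sensitivities (dB) of the two tests.
#' @export
test_retest_error <- function(ms1, ms2) {
  if (any(!is.finite(ms1)) || any(!is.finite(ms2))) {
    abort("Both mean sensitivities must be finite.")
  }
  abs(ms1 - ms2)
}

#' Extract clearly visible (suprathreshold) trials from a session
#'
#' Takes the session's final pointwise threshold estimates as the best guess
#' of the true sensitivity at each location and keeps every trial whose
#' stimulus was more than `margin_db` dB below threshold (i.e. brighter).
#' The default 3 dB margin is a doubling of stimulus intensity, well above
#' the ~1 dB spread of a typical frequency-of-seeing curve, so a miss on a
#' retained trial indicates a lapse rather than genuine non-detection. The
#' inequality is strict: a trial at exactly the margin is excluded.
#'
#' @param session A [vf_session()] object.
#' @param margin_db Required margin, dB (default 3).
#' @return A tibble with one row per visible trial: `trial`, `location_id`,
#'   `stimulus_db`, `onset_s`, `responded`, `latency_s`, `threshold_db`,
#'   `margin_db`, `outcome` ("hit"/"miss").
#' @export
extract_visible_trials <- function(session, margin_db = 3) {
  stopifnot(inherits(session, "vf_session"))
  trials <- session$trials
  thr <- dplyr::select(session$thresholds, "location_id", threshold_db = "dls_db")
  missing_loc <- setdiff(trials$location_id, thr$location_id)
  if (length(missing_loc) > 0) {
    abort(sprintf(
      "Trials reference location(s) absent from the threshold grid: %s",
      paste(missing_loc, collapse = ", ")
    ))
  }
  out <- dplyr::left_join(trials, thr, by = "location_id")
  out <- dplyr::mutate(out,
    margin_db = .data$threshold_db - .data$stimulus_db,
    outcome = dplyr::if_else(.data$responded, "hit", "miss")
  )
  dplyr::filter(out, .data$margin_db > !!margin_db)
}

#' Hit rate on a set of visible trials
#'
#' For stimuli comfortably above threshold the hit rate should be 1; the
#' shortfall is the lapse (false-negative) rate.
#'
#' @param visible A tibble from [extract_visible_trials()].
#' @return Proportion of hits in `[0, 1]`, or `NA_real_` for an empty set.
#' @export
hit_rate <- function(visible) {
  if (nrow(visible) == 0) return(NA_real_)
  mean(visible$outcome == "hit")
}
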