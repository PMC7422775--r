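#' Configuration for the synthetic session/cohort generator
#'
#' The generator emulates the data a webcam-monitored screen-perimetry
#' session produces: a 5 Hz stream of gaze/head/action-unit features whose
#' dispersion and intensity are modulated by a latent two-state attention
#' process (attentive / lapsed, a first-order Markov chain at the frame
#' level), and a trial log in which responses come from a
#' frequency-of-seeing observer whose miss probability is inflated while
#' lapsed. A scalar subject trait shifts the lapsed-state occupancy on the
#' log-odds scale, so that one latent quantity drives both biomarker
#' magnitude and measurement error, which is exactly the coupling the
#' analyses are designed to recover.
#'
#' Defaults mirror a typical assessment: 240 s at 5 Hz (~1200 frames), 24
#' locations x 6 presentations = 144 trials, baseline lapsed occupancy 0.15
#' with miss inflation 0.3 (expected visible-trial miss rate ~4.5%).
#'
#' @param seed Base seed; all session randomness derives from it.
#' @param n_subjects Number of subjects (one eye each), default 40.
#' @param sessions_per_subject 1 or 2 (default 2; two same-day tests).
#' @param frame_rate Hz, default 5.
#' @param duration_s Session length in seconds, default 240.
#' @param trials_per_location Presentations per grid location, default 6.
#' @param threshold_mean,threshold_sd Distribution of true pointwise
#'   thresholds, dB (defaults 28 and 2, healthy-like central field).
#' @param occupancy Baseline stationary probability of the lapsed state
#'   (default 0.15).
#' @param dwell_lapsed_frames Mean dwell time of a lapse, frames (default
#'   10, i.e. 2 s).
#' @param coupling Trait-to-occupancy log-odds slope (default 1). 0 removes
#'   all subject-level coupling.
#' @param lapse_inflation Probability a lapsed trial's response is
#'   suppressed (default 0.3).
#' @param attentive,lapsed Emission parameter lists (see defaults in the
#'   function signature): per-axis jitter SDs for gaze (deg), head location
#'   (mm) and head rotation (deg); mean/SD of expressive AU intensity and of
#'   blink (AU45) intensity; response latency mean/SD (s). `lapsed` gives
#'   multiplicative dispersion scales (must be >= 1) and its own AU/latency
#'   levels.
#' @param observer A [psychometric()] response model.
#' @param invalid_frame_rate Proportion of frames with failed face
#'   detection, default 0.02.
#' @param mode `"zest"` (default): thresholds are estimated by actually
#'   running the ZEST engine on the generated responses, so measurement
#'   error emerges mechanistically. `"shortcut"`: thresholds are the truth
#'   plus Gaussian noise of SD `ms_noise_sd * exp(coupling * trait)` — a
#'   fast path for unit tests.
#' @param ms_noise_sd Shortcut-mode pointwise threshold noise SD, dB
#'   (default 1).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1, n_subjects = 40, sessions_per_subject = 2,
                          frame_rate = 5, duration_s = 240,
                          trials_per_location = 6,
                          threshold_mean = 28, threshold_sd = 2,
                          occupancy = 0.15, dwell_lapsed_frames = 10,
                          coupling = 1, lapse_inflation = 0.3,
                          attentive = list(gaze_sd = 1.5, head_loc_sd = 4,
                                           head_rot_sd = 1.5,
                                           au_mean = 0.15, au_sd = 0.25,
                                           blink_mean = 0.3, blink_sd = 0.3,
                                           latency_mean = 0.45, latency_sd = 0.1),
                          lapsed = list(gaze_scale = 3, head_loc_scale = 3,
                                        head_rot_scale = 3,
                                        au_mean = 0.8, au_sd = 0.4,
                                        blink_mean = 1.0, blink_sd = 0.4,
                                        latency_mean = 0.9, latency_sd = 0.3),
                          observer = psychometric(),
                          invalid_frame_rate = 0.02,
                          mode = c("zest", "shortcut"), ms_noise_sd = 1) {
  mode <- match.arg(mode)
  if (n_subjects < 1) abort("n_subjects must be >= 1.")
  if (!sessions_per_subject %in% 1:2) abort("sessions_per_subject must be 1 or 2.")
  if (occupancy < 0 || occupancy > 1 || lapse_inflation < 0 || lapse_inflation > 1) {
    abort("occupancy and lapse_inflation must lie in [0, 1].")
  }
  scales <- unlist(lapsed[c("gaze_scale", "head_loc_scale", "head_rot_scale")])
  if (any(scales < 1)) {
    abort("Lapsed-state dispersion scales must be >= the attentive scale (>= 1).")
  }
  structure(
    list(seed = seed, n_subjects = n_subjects,
         sessions_per_subject = sessions_per_subject,
         frame_rate = frame_rate, duration_s = duration_s,
         trials_per_location = trials_per_location,
         threshold_mean = threshold_mean, threshold_sd = threshold_sd,
         occupancy = occupancy, dwell_lapsed_frames = dwell_lapsed_frames,
         coupling = coupling, lapse_inflation = lapse_inflation,
         attentive = attentive, lapsed = lapsed, observer = observer,
         invalid_frame_rate = invalid_frame_rate,
         mode = mode, ms_noise_sd = ms_noise_sd),
    class = "cohort_config"
  )
}

# Frame-level attention chain. Transition probabilities are parameterised by
# the stationary lapsed occupancy pi and the mean lapse dwell time:
# p(exit lapse) = 1/dwell, p(enter lapse) = p_exit * pi / (1 - pi).
simulate_attention_chain <- function(n, occupancy, dwell) {
  if (occupancy <= 0) return(rep(FALSE, n))
  if (occupancy >= 1) return(rep(TRUE, n))
  p_exit <- 1 / dwell
  p_enter <- min(p_exit * occupancy / (1 - occupancy), 1)
  state <- logical(n)
  state[1] <- runif(1) < occupancy
  u <- runif(n)
  for (i in seq_len(n - 1)) {
    state[i + 1] <- if (state[i]) u[i] >= p_exit else u[i] < p_enter
  }
  state
}

subject_occupancy <- function(config, trait) {
  if (config$occupancy <= 0 || config$occupancy >= 1) return(config$occupancy)
  stats::plogis(stats::qlogis(config$occupancy) + config$coupling * trait)
}

rtrunc_norm0 <- function(n, mean, sd) pmax(rnorm(n, mean, sd), 0)

#' Generate one synthetic session with ground truth
#'
#' See [cohort_config()] for the generative model. All randomness comes from
#' `seed`, so identical calls are bit-identical.
#'
#' @param config A [cohort_config()].
#' @param trait Subject compliance trait (z units; higher = less compliant).
#' @param truths Optional length-24 vector of true thresholds (dB); drawn
#'   from the config's distribution when `NULL`.
#' @param seed Integer seed for this session.
#' @param subject_id,eye Labels for the session.
#' @return A list with elements `session` (a [vf_session()]) and `truth`
#'   (frame states, per-trial states and forced-miss flags, trait, true
#'   thresholds, and the session's visible-trial bookkeeping).
#' @export
generate_session <- function(config, trait = 0, truths = NULL, seed = 1,
                             subject_id = "S01", eye = "OD") {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  att <- config$attentive
  lap <- config$lapsed
  n_frames <- round(config$duration_s * config$frame_rate)
  occ <- subject_occupancy(config, trait)
  state <- simulate_attention_chain(n_frames, occ, config$dwell_lapsed_frames)

  gaze_sd <- att$gaze_sd * ifelse(state, lap$gaze_scale, 1)
  loc_sd <- att$head_loc_sd * ifelse(state, lap$head_loc_scale, 1)
  rot_sd <- att$head_rot_sd * ifelse(state, lap$head_rot_scale, 1)
  au_mean <- ifelse(state, lap$au_mean, att$au_mean)
  au_sd <- ifelse(state, lap$au_sd, att$au_sd)
  blink_mean <- ifelse(state, lap$blink_mean, att$blink_mean)
  blink_sd <- ifelse(state, lap$blink_sd, att$blink_sd)

  frames <- tibble::tibble(
    frame = seq_len(n_frames),
    t = (seq_len(n_frames) - 1) / config$frame_rate,
    confidence = round(pmin(pmax(rnorm(n_frames, 0.95, 0.03), 0), 1), 4),
    valid = runif(n_frames) >= config$invalid_frame_rate,
    gaze_x = rnorm(n_frames, 0, gaze_sd),
    gaze_y = rnorm(n_frames, 0, gaze_sd),
    head_x = rnorm(n_frames, 0, loc_sd),
    head_y = rnorm(n_frames, -20, loc_sd),
    head_z = rnorm(n_frames, 450, loc_sd),
    head_pitch = rnorm(n_frames, 0, rot_sd),
    head_yaw = rnorm(n_frames, 0, rot_sd),
    head_roll = rnorm(n_frames, 0, rot_sd),
    au01 = rtrunc_norm0(n_frames, au_mean, au_sd),
    au02 = rtrunc_norm0(n_frames, au_mean, au_sd),
    au04 = rtrunc_norm0(n_frames, au_mean, au_sd),
    au15 = rtrunc_norm0(n_frames, au_mean, au_sd),
    au25 = rtrunc_norm0(n_frames, au_mean, au_sd),
    au26 = rtrunc_norm0(n_frames, au_mean, au_sd),
    au45 = rtrunc_norm0(n_frames, blink_mean, blink_sd)
  )
  frames$confidence[!frames$valid] <- round(runif(sum(!frames$valid), 0, 0.5), 4)

  if (is.null(truths)) {
    truths <- rnorm(24, config$threshold_mean, config$threshold_sd)
  }
  stopifnot(length(truths) == 24)

  n_trials <- 24 * config$trials_per_location
  schedule <- as.vector(vapply(seq_len(config$trials_per_location),
                               function(i) sample.int(24), integer(24)))
  onsets <- seq_len(n_trials) * config$duration_s / (n_trials + 1)
  frame_at <- pmin(pmax(floor(onsets * config$frame_rate) + 1, 1), n_frames)
  trial_state <- state[frame_at]

  stimulus <- numeric(n_trials)
  responded <- logical(n_trials)
  forced_miss <- logical(n_trials)
  zstates <- NULL
  if (config$mode == "zest") {
    zstates <- lapply(seq_len(24), function(i) zest_state(model = config$observer))
  }
  for (i in seq_len(n_trials)) {
    loc <- schedule[i]
    stim <- if (config$mode == "zest") {
      select_stimulus(zstates[[loc]])
    } else {
      truths[loc] + sample(c(-8, -6, -4, -2, 0, 2), 1)
    }
    seen <- runif(1) < p_seen(config$observer, truths[loc], stim)
    fm <- trial_state[i] && runif(1) < config$lapse_inflation
    resp <- seen && !fm
    stimulus[i] <- stim
    responded[i] <- resp
    forced_miss[i] <- fm && seen
    if (config$mode == "zest") {
      zstates[[loc]] <- zest_update(zstates[[loc]], stim, resp, alpha = 1)
    }
  }
  lat_mean <- ifelse(trial_state, lap$latency_mean, att$latency_mean)
  lat_sd <- ifelse(trial_state, lap$latency_sd, att$latency_sd)
  latency <- pmax(rnorm(n_trials, lat_mean, lat_sd), 0.15)
  latency[!responded] <- NA_real_

  trials <- tibble::tibble(
    trial = seq_len(n_trials), location_id = schedule,
    stimulus_db = stimulus, onset_s = onsets,
    responded = responded, latency_s = latency
  )

  grid <- grid_24_2_central()
  grid$dls_db <- if (config$mode == "zest") {
    vapply(zstates, posterior_mean, numeric(1))
  } else {
    truths + rnorm(24, 0, config$ms_noise_sd * exp(config$coupling * trait))
  }

  session <- vf_session(frames, trials, grid, subject_id = subject_id,
                        eye = eye, frame_rate = config$frame_rate, quiet = TRUE)
  visible <- extract_visible_trials(session)
  truth <- list(
    trait = trait,
    occupancy = occ,
    frame_lapsed = state,
    trial_lapsed = trial_state,
    forced_miss = forced_miss,
    true_thresholds = truths,
    visible_trial_count = nrow(visible)
  )
  list(session = session, truth = truth)
}

#' Generate a cohort of repeatedly tested synthetic eyes
#'
#' Draws one compliance trait per subject from N(0, 1), one set of true
#' thresholds per subject, and `sessions_per_subject` sessions per subject
#' with that trait. Returns both the raw sessions (with ground truth) and
#' the per-eye analysis table: biomarkers mean-averaged across the repeat
#' sessions, the two mean sensitivities and their absolute difference
#' (`error`, dB).
#'
#' @param config A [cohort_config()].
#' @return A list with `subjects` (list of `list(sessions, truth)`) and
#'   `cohort` (one tibble row per eye).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  traits <- rnorm(config$n_subjects)
  truth_sets <- lapply(seq_len(config$n_subjects), function(i) {
    rnorm(24, config$threshold_mean, config$threshold_sd)
  })
  subjects <- vector("list", config$n_subjects)
  rows <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    sessions <- lapply(seq_len(config$sessions_per_subject), function(k) {
      generate_session(config, trait = traits[s], truths = truth_sets[[s]],
                       seed = config$seed + 1009L * s + k,
                       subject_id = sid, eye = "OD")
    })
    bm <- dplyr::bind_rows(lapply(sessions, function(x) session_biomarkers(x$session)))
    bm_avg <- dplyr::summarise(
      bm, dplyr::across(dplyr::all_of(biomarker_names()), ~ mean(.x, na.rm = TRUE))
    )
    ms <- vapply(sessions, function(x) mean_sensitivity(x$session$thresholds),
                 numeric(1))
    err <- if (length(ms) == 2) test_retest_error(ms[1], ms[2]) else NA_real_
    rows[[s]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = sid, eye = "OD", trait = traits[s],
                     ms1 = ms[1], ms2 = ms[length(ms)], error = err),
      bm_avg
    )
    subjects[[s]] <- list(
      sessions = lapply(sessions, `[[`, "session"),
      truths = lapply(sessions, `[[`, "truth")
    )
  }
  list(subjects = subjects, cohort = dplyr::bind_rows(rows))
}

#' Flatten a generated cohort into a list of sessions
#'
#' @param cohort Output of [generate_cohort()].
#' @return A flat list of `vf_session` objects.
#' @export
cohort_sessions <- function(cohort) {
  unlist(lapply(cohort$subjects, `[[`, "sessions"), recursive = FALSE)
}
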