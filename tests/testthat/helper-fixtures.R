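# In-code fixtures and independent oracles shared across test files.

# Frame tibble in the package's internal layout. Scalars are recycled.
make_frames <- function(n = 10, frame_rate = 5, valid = TRUE,
                        gaze_x = 0, gaze_y = 0,
                        head_x = 0, head_y = 0, head_z = 450,
                        head_pitch = 0, head_yaw = 0, head_roll = 0,
                        au01 = 0, au02 = 0, au04 = 0, au15 = 0,
                        au25 = 0, au26 = 0, au45 = 0,
                        confidence = 0.95) {
  tibble::tibble(
    frame = seq_len(n), t = (seq_len(n) - 1) / frame_rate,
    confidence = rep_len(confidence, n), valid = rep_len(valid, n),
    gaze_x = rep_len(gaze_x, n), gaze_y = rep_len(gaze_y, n),
    head_x = rep_len(head_x, n), head_y = rep_len(head_y, n),
    head_z = rep_len(head_z, n),
    head_pitch = rep_len(head_pitch, n), head_yaw = rep_len(head_yaw, n),
    head_roll = rep_len(head_roll, n),
    au01 = rep_len(au01, n), au02 = rep_len(au02, n), au04 = rep_len(au04, n),
    au15 = rep_len(au15, n), au25 = rep_len(au25, n), au26 = rep_len(au26, n),
    au45 = rep_len(au45, n)
  )
}

make_trials <- function(stimulus_db, location_id = 1, onset_s = NULL,
                        responded = TRUE, latency_s = NULL) {
  n <- length(stimulus_db)
  responded <- rep_len(responded, n)
  if (is.null(onset_s)) onset_s <- seq_len(n) * 0.5
  if (is.null(latency_s)) latency_s <- ifelse(responded, 0.5, NA_real_)
  tibble::tibble(
    trial = seq_len(n), location_id = rep_len(location_id, n),
    stimulus_db = stimulus_db, onset_s = onset_s,
    responded = responded, latency_s = latency_s
  )
}

make_grid <- function(db = 30) {
  g <- grid_24_2_central()
  g$dls_db <- rep_len(db, 24)
  g
}

make_session <- function(frames = make_frames(20), trials = make_trials(25),
                         grid = make_grid(), ...) {
  vf_session(frames, trials, grid, quiet = TRUE, ...)
}

# Independent brute-force Sn oracle: explicit enumeration of all pairwise
# Euclidean distances, medians taken with stats::median.
sn_oracle <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  inner <- numeric(n)
  for (i in seq_len(n)) {
    d <- numeric(n - 1)
    k <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      k <- k + 1
      d[k] <- sqrt(sum((x[i, ] - x[j, ])^2))
    }
    inner[i] <- median(d)
  }
  median(inner)
}

# Reference posterior update with the compliance-weighting code removed:
# the same log-space Bayes step, no alpha anywhere.
ref_unweighted_update <- function(state, stimulus, responded) {
  p <- p_seen(state$model, state$domain, stimulus)
  ll <- if (responded) log(p) else log1p(-p)
  lp <- state$log_post + ll
  lp <- lp - max(lp)
  lp - log(sum(exp(lp)))
}
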