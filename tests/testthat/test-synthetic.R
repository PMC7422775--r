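fast_cfg <- function(...) {
  args <- list(duration_s = 30, trials_per_location = 2, mode = "shortcut")
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

test_that("identical seeds reproduce sessions bit-identically", {
  cfg <- fast_cfg()
  a <- generate_session(cfg, trait = 0.5, seed = 7)
  b <- generate_session(cfg, trait = 0.5, seed = 7)
  expect_identical(a$session$frames, b$session$frames)
  expect_identical(a$session$trials, b$session$trials)
  expect_identical(a$session$thresholds, b$session$thresholds)
  expect_identical(a$truth, b$truth)
  c <- generate_session(cfg, trait = 0.5, seed = 8)
  expect_false(identical(a$session$frames, c$session$frames))
})

test_that("the attention chain honours its stationary occupancy", {
  set.seed(41)
  state <- complimetry:::simulate_attention_chain(1e5, occupancy = 0.2, dwell = 10)
  expect_lt(abs(mean(state) - 0.2), 0.01)

  # zero lapse probability -> fully attentive, no forced misses
  g <- generate_session(fast_cfg(occupancy = 0), seed = 3)
  expect_false(any(g$truth$frame_lapsed))
  expect_false(any(g$truth$forced_miss))
})

test_that("forced misses occur only in the lapsed state", {
  cfg <- fast_cfg(occupancy = 0.4, lapse_inflation = 0.8,
                  trials_per_location = 4)
  g <- generate_session(cfg, seed = 13)
  expect_true(any(g$truth$forced_miss))  # enough lapses to matter
  expect_true(all(g$truth$trial_lapsed[g$truth$forced_miss]))
  # lapsed dispersion scales below 1 are rejected
  expect_error(cohort_config(lapsed = list(gaze_scale = 0.5, head_loc_scale = 3,
                                           head_rot_scale = 3, au_mean = 1,
                                           au_sd = 1, blink_mean = 1,
                                           blink_sd = 1, latency_mean = 1,
                                           latency_sd = 0.1)),
               ">= 1")
})

test_that("visible-trial hit rate matches the lapse-mixture closed form", {
  # occupancy 0.5, miss inflation 0.5, near-perfect observer on bright
  # stimuli: P(hit) = 1 - 0.5 * 0.5 = 0.75
  cfg <- cohort_config(duration_s = 2016, trials_per_location = 84,
                       frame_rate = 5, mode = "shortcut", occupancy = 0.5,
                       lapse_inflation = 0.5, coupling = 0, ms_noise_sd = 0,
                       observer = psychometric(sigma = 0.5, gamma = 0, lambda = 0))
  g <- generate_session(cfg, seed = 17)
  vt <- extract_visible_trials(g$session)
  expect_gt(nrow(vt), 800)
  expect_equal(hit_rate(vt), 0.75, tolerance = 0.05)
})

test_that("matched emission parameters remove the state difference", {
  # dispersion scales forced to 1 and AU/latency levels equalised: windowed
  # gaze variability should not differ between lapsed and attentive trials
  att <- list(gaze_sd = 1.5, head_loc_sd = 4, head_rot_sd = 1.5,
              au_mean = 0.3, au_sd = 0.3, blink_mean = 0.3, blink_sd = 0.3,
              latency_mean = 0.5, latency_sd = 0.1)
  lap <- list(gaze_scale = 1, head_loc_scale = 1, head_rot_scale = 1,
              au_mean = 0.3, au_sd = 0.3, blink_mean = 0.3, blink_sd = 0.3,
              latency_mean = 0.5, latency_sd = 0.1)
  cfg <- cohort_config(duration_s = 120, trials_per_location = 6,
                       mode = "shortcut", occupancy = 0.5,
                       attentive = att, lapsed = lap)
  g <- generate_session(cfg, seed = 29)
  w <- windowed_biomarkers(g$session)
  by_state <- split(w$gaze_variability, g$truth$trial_lapsed[order(g$session$trials$onset_s)])
  expect_gt(stats::t.test(by_state[[1]], by_state[[2]])$p.value, 0.05)
})

test_that("trait coupling is required for a biomarker-error correlation", {
  # coupling 0: no subject-level link between biomarkers and error
  cfg0 <- fast_cfg(n_subjects = 40, coupling = 0, seed = 51)
  coh0 <- generate_cohort(cfg0)
  a0 <- testretest_association(coh0$cohort)
  r0 <- tidy(a0)$r[tidy(a0)$term == "composite"]
  expect_lt(abs(r0), 0.35)

  # strong coupling: the composite recovers the association
  cfg1 <- fast_cfg(n_subjects = 40, coupling = 1.5, seed = 52,
                   duration_s = 60, ms_noise_sd = 0.6)
  coh1 <- generate_cohort(cfg1)
  a1 <- testretest_association(coh1$cohort)
  comp <- dplyr::filter(tidy(a1), term == "composite")
  expect_gt(comp$r, 0.3)
  expect_lt(comp$p_value, 0.05)

  # two sessions per subject -> one averaged row per eye
  expect_equal(nrow(coh1$cohort), 40)
  expect_equal(length(cohort_sessions(coh1)), 80)
})

test_that("cohort analyses rank informative biomarkers above uninformative", {
  # expression AUs equalised across states: sadness and surprise carry no
  # signal, while the dispersion and blink channels do
  att <- list(gaze_sd = 1.5, head_loc_sd = 4, head_rot_sd = 1.5,
              au_mean = 0.3, au_sd = 0.3, blink_mean = 0.3, blink_sd = 0.3,
              latency_mean = 0.45, latency_sd = 0.1)
  lap <- list(gaze_scale = 3, head_loc_scale = 3, head_rot_scale = 3,
              au_mean = 0.3, au_sd = 0.3, blink_mean = 1.2, blink_sd = 0.4,
              latency_mean = 0.9, latency_sd = 0.3)
  informative <- c("gaze_variability", "head_location_variability",
                   "head_rotation_variability", "blink_rate")
  uninformative <- c("mean_sadness", "mean_surprise")

  wins <- 0L
  for (rep in 1:50) {
    cfg <- cohort_config(n_subjects = 25, duration_s = 30,
                         trials_per_location = 1, mode = "shortcut",
                         coupling = 1.5, ms_noise_sd = 0.6,
                         attentive = att, lapsed = lap, seed = 100 + rep)
    coh <- generate_cohort(cfg)
    r <- vapply(c(informative, uninformative),
                function(b) abs(cor(coh$cohort[[b]], coh$cohort$error)),
                numeric(1))
    if (min(r[informative]) > max(r[uninformative])) wins <- wins + 1L
  }
  expect_gte(wins, 45)  # >= 90% of replicates
})
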