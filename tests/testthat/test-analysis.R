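test_that("geometric-mean regression matches its closed form", {
  fit <- gm_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)

  # slope sign follows r; magnitude is the SD ratio regardless of r
  set.seed(61)
  x <- rnorm(30); y <- -2 * x + rnorm(30, sd = 0.1)
  fit <- gm_regression(x, y)
  expect_lt(fit$slope, 0)
  expect_equal(abs(fit$slope), sd(y) / sd(x))

  # equivariance under axis rescaling
  fit2 <- gm_regression(x / 10, y * 3)
  expect_equal(fit2$slope, fit$slope * 30)
  expect_error(gm_regression(rep(1, 5), 1:5), "zero-variance")
})

test_that("test-retest association recovers exact linear relations", {
  tbl <- tibble::tibble(
    gaze_variability = c(1, 2, 3, 4, 5),
    blink_rate = c(2, 1, 4, 3, 5),
    error = 3 * c(1, 2, 3, 4, 5)  # exactly proportional to gaze variability
  )
  res <- testretest_association(tbl, biomarkers = c("gaze_variability", "blink_rate"))
  g <- tidy(res)[tidy(res)$term == "gaze_variability", ]
  expect_equal(g$r, 1)
  expect_equal(g$slope, 3)
  expect_equal(g$intercept, 0, tolerance = 1e-12)

  # Pearson r invariant under affine rescaling; slope equivariant
  tbl2 <- dplyr::mutate(tbl, gaze_variability = 10 * gaze_variability + 5)
  res2 <- testretest_association(tbl2, biomarkers = c("gaze_variability", "blink_rate"))
  g2 <- tidy(res2)[tidy(res2)$term == "gaze_variability", ]
  expect_equal(g2$r, g$r)
  expect_equal(g2$slope, g$slope / 10)

  expect_error(
    testretest_association(dplyr::mutate(tbl, blink_rate = 1),
                           biomarkers = c("gaze_variability", "blink_rate")),
    "blink_rate"
  )
  expect_error(testretest_association(tbl[1:3, ],
                                      biomarkers = "gaze_variability"),
               "at least 4")
})

test_that("manual outlier exclusion is applied and logged", {
  set.seed(62)
  tbl <- tibble::tibble(gaze_variability = rnorm(10, 5),
                        blink_rate = rnorm(10, 5))
  tbl$error <- tbl$gaze_variability + rnorm(10, sd = 0.3)
  tbl$error[10] <- 50  # conspicuous outlier
  expect_message(
    res <- testretest_association(tbl, exclude = 10,
                                  biomarkers = c("gaze_variability", "blink_rate")),
    "outliers"
  )
  expect_equal(nrow(res$excluded), 1)
  expect_equal(max(tidy(res)$n), 9)
  expect_equal(glance(res)$n_excluded, 1)
})

test_that("the trialwise table pools visible trials and drops bad windows", {
  s <- make_session(
    frames = make_frames(30, au45 = 0.4),
    trials = make_trials(c(25, 26, 27, 28), onset_s = c(1, 2, 3, 4)),
    grid = make_grid(30)
  )
  tw <- trialwise_dataset(list(s))
  expect_equal(nrow(tw), 2)  # the two >3 dB trials
  expect_true(all(tw$hit))
  expect_true(all(complimetry:::video_biomarker_names() %in% names(tw)))

  # a session whose trials are all near threshold contributes nothing
  s2 <- make_session(trials = make_trials(c(29, 30), onset_s = c(1, 2)),
                     grid = make_grid(30))
  expect_warning(tw2 <- trialwise_dataset(list(s2)), "no visible trials")
  expect_equal(nrow(tw2), 0)
})

test_that("lapse models recover a known logistic dependence", {
  set.seed(63)
  n <- 5000
  b <- runif(n, 0, 2)
  hit <- runif(n) < 1 / (1 + exp(-(3 - 2 * b)))
  tbl <- tibble::tibble(hit = hit, gaze_variability = b)
  fit <- fit_lapse_model(tbl, "gaze_variability")
  sl <- glance(fit)$slope
  se <- tidy(fit)$std_error[2]
  expect_lt(abs(sl - (-2)), 1.96 * se)  # truth inside the fit's 95% CI
  expect_lt(glance(fit)$p_value, 1e-6)
  expect_false(glance(fit)$separation)

  # binning conserves the rows and CIs contain the point estimates
  expect_equal(sum(fit$bins$n), n)
  expect_true(all(fit$bins$lower <= fit$bins$hit_rate + 1e-12 &
                  fit$bins$hit_rate <= fit$bins$upper + 1e-12))
})

test_that("mean recovered slope is within 5% of truth across replicates", {
  slopes <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    b <- runif(5000, 0, 2)
    hit <- runif(5000) < 1 / (1 + exp(-(3 - 2 * b)))
    glance(fit_lapse_model(tibble::tibble(hit = hit, gaze_variability = b),
                           "gaze_variability"))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-2)), 0.05 * 2)
})

test_that("independent outcomes give a flat, non-significant lapse model", {
  set.seed(64)
  tbl <- tibble::tibble(hit = runif(2000) < 0.95,
                        gaze_variability = runif(2000, 0.1, 2))
  fit <- fit_lapse_model(tbl, "gaze_variability")
  expect_lt(abs(glance(fit)$slope), 0.5)
  expect_gt(glance(fit)$p_value, 0.05)
})

test_that("degenerate outcome patterns are flagged, not reported as fits", {
  # perfectly separated data -> separation flag, no p-value
  tbl <- tibble::tibble(
    hit = c(rep(FALSE, 5), rep(TRUE, 50)),
    gaze_variability = c(seq(0.1, 0.5, length.out = 5),
                         seq(1, 5, length.out = 50))
  )
  fit <- fit_lapse_model(tbl, "gaze_variability")
  expect_true(fit$separation)
  expect_true(is.na(fit$p_value))

  # all hits: no misses to model at all
  all_hits <- tibble::tibble(hit = rep(TRUE, 20), gaze_variability = runif(20))
  expect_error(fit_lapse_model(all_hits, "gaze_variability"), "2 hits and 2 misses")

  # non-positive biomarker values are binned low and logged
  set.seed(65)
  tbl2 <- tibble::tibble(hit = runif(500) < 0.9,
                         gaze_variability = c(rep(0, 5), runif(495, 0.5, 2)))
  expect_message(fit2 <- fit_lapse_model(tbl2, "gaze_variability"),
                 "first bin")
  expect_equal(sum(fit2$bins$n), 500)
})
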