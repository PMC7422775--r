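test_that("the psychometric model behaves as a guarded cumulative Gaussian", {
  m <- psychometric(sigma = 1, gamma = 0.05, lambda = 0.1)
  expect_equal(p_seen(m, 25, 25), 0.05 + 0.85 * 0.5)     # midpoint
  expect_equal(p_seen(m, 25, -100), 0.90, tolerance = 1e-9)  # plateau 1 - lambda
  diffs <- p_seen(m, 25, seq(40, 0, by = -0.5))
  expect_true(all(diff(diffs) >= 0))                      # monotone in T - s
  expect_error(psychometric(sigma = 0), "sigma")
  expect_error(psychometric(gamma = 0.6, lambda = 0.5), "gamma")
})

test_that("posterior updates follow weighted Bayes and stay normalised", {
  m <- psychometric(sigma = 1, gamma = 0, lambda = 0)
  st <- zest_state(domain = c(20, 30), model = m)
  up <- zest_update(st, 25, TRUE, alpha = 1)
  expect_equal(sum(zest_posterior(up)), 1, tolerance = 1e-12)
  # P(30 | seen at 25) = Phi(5) / (Phi(5) + Phi(-5)), computed independently
  expect_equal(zest_posterior(up)[2], pnorm(5) / (pnorm(5) + pnorm(-5)),
               tolerance = 1e-12)

  # alpha = 0 leaves the posterior bit-identical
  z0 <- zest_update(st, 25, TRUE, alpha = 0)
  expect_identical(z0$log_post, st$log_post)
  expect_equal(nrow(z0$history), 1)  # but the trial is still recorded

  # alpha = 1 is bit-identical to the same update with the weighting removed
  set.seed(42)
  st2 <- zest_state(model = psychometric())
  for (i in 1:50) {
    stim <- sample(st2$domain, 1)
    resp <- runif(1) < 0.5
    expect_identical(zest_update(st2, stim, resp, alpha = 1)$log_post,
                     ref_unweighted_update(st2, stim, resp))
    st2 <- zest_update(st2, stim, resp, alpha = 1)
  }

  expect_error(zest_update(st, 25, TRUE, alpha = 2), "\\[0, 1\\]")
})

test_that("partial weighting interpolates between ignoring and full Bayes", {
  m <- psychometric(sigma = 1, gamma = 0, lambda = 0)
  st <- zest_state(domain = c(20, 30), model = m)
  prior <- zest_posterior(st)
  kl <- function(p, q) sum(ifelse(p > 0, p * log(p / q), 0))
  p0 <- zest_posterior(zest_update(st, 25, TRUE, alpha = 0))
  p_half <- zest_posterior(zest_update(st, 25, TRUE, alpha = 0.5))
  p1 <- zest_posterior(zest_update(st, 25, TRUE, alpha = 1))
  expect_equal(kl(p0, prior), 0)
  expect_gt(kl(p_half, prior), kl(p0, prior))
  expect_gt(kl(p1, prior), kl(p_half, prior))
})

test_that("likelihood accumulation is order-free and batch-equivalent", {
  m <- psychometric()
  set.seed(9)
  stims <- sample(seq(15, 35, 0.5), 12, replace = TRUE)
  resps <- runif(12) < 0.6

  # sequential updates
  st <- zest_state(model = m)
  for (i in seq_along(stims)) st <- zest_update(st, stims[i], resps[i], alpha = 1)

  # batch: single product of likelihoods over the full history
  lp <- log(rep(1 / length(st$domain), length(st$domain)))
  for (i in seq_along(stims)) {
    p <- p_seen(m, st$domain, stims[i])
    lp <- lp + if (resps[i]) log(p) else log1p(-p)
  }
  batch <- exp(lp - max(lp)); batch <- batch / sum(batch)
  expect_equal(zest_posterior(st), batch, tolerance = 1e-9)

  # a hit and a miss at the same stimulus commute
  a <- zest_update(zest_update(st, 25, TRUE), 25, FALSE)
  b <- zest_update(zest_update(st, 25, FALSE), 25, TRUE)
  expect_equal(zest_posterior(a), zest_posterior(b), tolerance = 1e-12)
})

test_that("stimulus placement rules pick sensible levels", {
  st <- zest_state(domain = seq(0, 40, 0.5))
  expect_equal(select_stimulus(st, "posterior_mean"), 20)  # uniform -> centre

  point <- zest_state(domain = seq(0, 40, 0.5),
                      prior = as.numeric(seq(0, 40, 0.5) == 27))
  expect_equal(select_stimulus(point, "posterior_mean"), 27)

  # min-entropy on a two-hypothesis posterior probes between the hypotheses
  m <- psychometric(sigma = 1, gamma = 0, lambda = 0)
  two <- zest_state(domain = seq(0, 40, 0.5),
                    prior = as.numeric(seq(0, 40, 0.5) %in% c(20, 30)),
                    model = m)
  s <- select_stimulus(two, "min_entropy")
  expect_gt(s, 20)
  expect_lt(s, 30)
})

test_that("stopping criteria distinguish certainty from exhaustion", {
  st <- zest_state()
  expect_false(stopping_met(st, max_trials = 5)$stop)
  # uniform posterior on 0-40 is nowhere near 0.1 nats
  expect_false(stopping_met(st, max_trials = 5, entropy_target = 0.1)$stop)

  narrow <- zest_state(domain = seq(0, 40, 0.5),
                       prior = stats::dnorm(seq(0, 40, 0.5), 25, 0.4))
  expect_lte(posterior_sd(narrow), 0.5)
  expect_true(stopping_met(narrow, sd_target = 0.5)$stop)
  expect_false(stopping_met(narrow, sd_target = 0.5)$did_not_complete)

  # cap reached with an unmet accuracy target -> did not complete
  st <- zest_update(st, 20, TRUE)
  res <- stopping_met(st, max_trials = 1, sd_target = 0.5)
  expect_true(res$stop)
  expect_true(res$did_not_complete)
})

test_that("the simulated observer matches its closed-form response rates", {
  m0 <- psychometric(sigma = 1, gamma = 0, lambda = 0)
  set.seed(123)
  expect_true(all(simulate_observer(25, m0, rep(5, 200))))  # 20 dB suprathreshold

  m_lapse <- psychometric(sigma = 1, gamma = 0, lambda = 0.97)
  set.seed(124)
  # lapse rate pushed to the ceiling: response probability <= 0.03
  expect_lt(mean(simulate_observer(25, m_lapse, rep(5, 500))), 0.08)

  # at threshold the response rate is gamma + (1 - gamma - lambda) / 2
  m <- psychometric(sigma = 1, gamma = 0.05, lambda = 0.05)
  set.seed(125)
  frac <- mean(simulate_observer(25, m, rep(25, 10000)))
  expect_equal(frac, 0.05 + 0.9 / 2, tolerance = 3 * sqrt(0.25 / 10000) + 0.005)

  # a lapsed observer with full suppression never responds
  set.seed(126)
  expect_false(any(simulate_observer(25, m0, rep(5, 200), lapsed = TRUE,
                                     lapse_inflation = 1)))
})

test_that("threshold estimation converges for a compliant observer", {
  set.seed(2024)
  fit <- run_threshold_estimation(25, psychometric(sigma = 1), n_trials = 30)
  expect_lte(abs(fit$estimate - 25), 1)
  expect_equal(nrow(fit$trace), 30)
  expect_true(all(fit$trace$alpha == 1))
  expect_false(fit$did_not_complete)

  # posterior SD shrinks over the run
  expect_lt(dplyr::last(fit$trace$posterior_sd), fit$trace$posterior_sd[1])

  # mean absolute error over many seeds at 60 trials is small
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    run_threshold_estimation(27.3, psychometric(), n_trials = 60)$estimate - 27.3
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.3)
})

test_that("zeroing the weight on lapsed trials removes their damage", {
  demo <- pipeline_zest_demo(n_reps = 40, seed = 3)
  expect_lt(demo$rmse[demo$arm == "weighted"], demo$rmse[demo$arm == "naive"])
  # naive runs are biased downwards by suppressed responses
  expect_lt(demo$bias[demo$arm == "naive"], demo$bias[demo$arm == "weighted"])
})

test_that("compliance weights map z-scores onto [0, 1] monotonically", {
  expect_equal(alpha_from_compliance(1e6), 0)
  expect_equal(alpha_from_compliance(-1e6), 1)
  expect_equal(alpha_from_compliance(1, k = 2, theta0 = 1), 0.5)
  theta <- seq(-4, 4, 0.1)
  a <- alpha_from_compliance(theta, k = 0.7)
  expect_true(all(diff(a) <= 0))
  expect_true(all(a >= 0 & a <= 1))
  expect_error(alpha_from_compliance(NA_real_), "finite")
  expect_error(alpha_from_compliance(0, k = -1), "k")
})
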