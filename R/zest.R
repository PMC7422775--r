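#' Cumulative-Gaussian frequency-of-seeing model
#'
#' Detection probability for a stimulus at `s` dB given a true threshold
#' `T` dB:
#' \deqn{p(\mathrm{seen}) = \gamma + (1 - \gamma - \lambda)\,\Phi((T - s)/\sigma)}
#' where \eqn{\sigma} is the frequency-of-seeing slope (~1 dB at healthy
#' locations), \eqn{\gamma} the guess rate and \eqn{\lambda} the lapse rate.
#' Because perimetric dB measure attenuation, stimuli *below* threshold in
#' dB are brighter, hence detection probability increases with `T - s`.
#'
#' @param sigma Slope in dB (> 0).
#' @param gamma Guess rate in `[0, 1)`.
#' @param lambda Lapse rate in `[0, 1)`; `gamma + lambda < 1`.
#' @return An object of class `psychometric`.
#' @export
psychometric <- function(sigma = 1, gamma = 0.03, lambda = 0.03) {
  if (!(sigma > 0)) abort("FOS slope sigma must be > 0 dB.")
  if (gamma < 0 || gamma >= 1 || lambda < 0 || lambda >= 1 || gamma + lambda >= 1) {
    abort("Need 0 <= gamma, lambda and gamma + lambda < 1.")
  }
  structure(list(sigma = sigma, gamma = gamma, lambda = lambda),
            class = "psychometric")
}

#' Probability of seeing under a frequency-of-seeing model
#'
#' @param model A [psychometric()] object.
#' @param threshold True threshold(s), dB.
#' @param stimulus Stimulus level(s), dB.
#' @return Detection probabilities.
#' @export
p_seen <- function(model, threshold, stimulus) {
  stopifnot(inherits(model, "psychometric"))
  model$gamma +
    (1 - model$gamma - model$lambda) * pnorm((threshold - stimulus) / model$sigma)
}

#' Initialise a ZEST state
#'
#' ZEST (Zippy Estimation by Sequential Testing) maintains a posterior
#' probability mass over a discrete grid of candidate thresholds and updates
#' it by Bayes' rule after every stimulus presentation. Mass is accumulated
#' in log space to avoid underflow over long trial sequences.
#'
#' @param domain Candidate thresholds in dB (default 0-40 in 0.5 dB steps).
#' @param prior Prior mass over `domain` (default uniform); normalised
#'   internally. A bimodal or normative prior can be supplied here.
#' @param model The [psychometric()] response model used for likelihoods.
#' @return An object of class `zest_state` with elements `domain`,
#'   `log_post`, `model` and a `history` tibble of
#'   (stimulus, responded, alpha, posterior_sd).
#' @export
zest_state <- function(domain = seq(0, 40, by = 0.5), prior = NULL,
                       model = psychometric()) {
  if (is.null(prior)) prior <- rep(1, length(domain))
  if (length(prior) != length(domain) || any(prior < 0) || sum(prior) <= 0) {
    abort("Prior must be a non-negative mass over the domain with positive total.")
  }
  structure(
    list(
      domain = as.numeric(domain),
      log_post = log(prior / sum(prior)),
      model = model,
      history = tibble::tibble(
        stimulus = numeric(), responded = logical(),
        alpha = numeric(), posterior_sd = numeric()
      )
    ),
    class = "zest_state"
  )
}

#' Posterior mass of a ZEST state
#' @param state A `zest_state`.
#' @return Normalised probability vector over `state$domain`.
#' @export
zest_posterior <- function(state) {
  lp <- state$log_post - max(state$log_post)
  p <- exp(lp)
  p / sum(p)
}

#' @rdname zest_posterior
#' @export
posterior_mean <- function(state) sum(zest_posterior(state) * state$domain)

#' @rdname zest_posterior
#' @export
posterior_mode <- function(state) state$domain[which.max(zest_posterior(state))]

#' @rdname zest_posterior
#' @export
posterior_sd <- function(state) {
  p <- zest_posterior(state)
  m <- sum(p * state$domain)
  sqrt(max(0, sum(p * (state$domain - m)^2)))
}

#' @rdname zest_posterior
#' @export
posterior_entropy <- function(state) {
  p <- zest_posterior(state)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Compliance-weighted Bayesian update of a ZEST posterior
#'
#' Standard ZEST multiplies the posterior by the likelihood of the observed
#' response. Here each trial's likelihood term is additionally raised to a
#' compliance weight `alpha` in `[0, 1]` (equivalently, `alpha` multiplies
#' the log-likelihood): `alpha = 1` is the usual Bayes update, `alpha = 0`
#' discards the trial entirely and leaves the posterior untouched, and
#' intermediate values give the response partial credit. Down-weighting
#' responses judged non-compliant keeps a single unreliable button press (or
#' absence of one) from corrupting the threshold estimate.
#'
#' @param state A [zest_state()].
#' @param stimulus Stimulus level, dB.
#' @param responded Logical; did the participant respond?
#' @param alpha Compliance weight in `[0, 1]`.
#' @return The updated `zest_state` (posterior renormalised; history row
#'   appended).
#' @export
zest_update <- function(state, stimulus, responded, alpha = 1) {
  stopifnot(inherits(state, "zest_state"))
  if (!is.finite(stimulus)) abort("Stimulus level must be finite.")
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    abort("Compliance weight alpha must lie in [0, 1].")
  }
  if (alpha > 0) {
    p <- p_seen(state$model, state$domain, stimulus)
    ll <- if (isTRUE(responded)) log(p) else log1p(-p)
    lp <- state$log_post + alpha * ll
    if (!any(is.finite(lp))) {
      abort(paste(
        "Posterior mass vanished after the update (numerical underflow):",
        "the response has zero likelihood everywhere on the domain."
      ))
    }
    lp <- lp - max(lp)
    state$log_post <- lp - log(sum(exp(lp)))
  }
  state$history <- dplyr::bind_rows(
    state$history,
    tibble::tibble(
      stimulus = stimulus, responded = isTRUE(responded),
      alpha = alpha, posterior_sd = NA_real_
    )
  )
  state$history$posterior_sd[nrow(state$history)] <- posterior_sd(state)
  state
}

#' Choose the next stimulus level
#'
#' The default ZEST placement presents at the current posterior mean
#' (snapped to the domain grid). The `min_entropy` rule instead sweeps the
#' domain and picks the stimulus minimising the expected posterior entropy
#' over the two possible responses — the most informative presentation.
#'
#' @param state A [zest_state()].
#' @param rule `"posterior_mean"` (default) or `"min_entropy"`.
#' @return A stimulus level from `state$domain`, dB.
#' @export
select_stimulus <- function(state, rule = c("posterior_mean", "min_entropy")) {
  rule <- match.arg(rule)
  if (rule == "posterior_mean") {
    m <- posterior_mean(state)
    return(state$domain[which.min(abs(state$domain - m))])
  }
  post <- zest_posterior(state)
  exp_H <- vapply(state$domain, function(s) {
    p_T <- p_seen(state$model, state$domain, s)
    p_yes <- sum(post * p_T)
    h_given <- function(post_new) {
      post_new <- post_new / sum(post_new)
      q <- post_new[post_new > 0]
      -sum(q * log(q))
    }
    yes <- post * p_T
    no <- post * (1 - p_T)
    p_yes * h_given(yes) + (1 - p_yes) * h_given(no)
  }, numeric(1))
  state$domain[which.min(exp_H)]
}

#' Has the stopping criterion been met?
#'
#' Supported criteria: a trial-count cap, a posterior-SD target, and a
#' posterior-entropy target (nats). If the cap is reached while an accuracy
#' target remains unmet the run is flagged `did_not_complete` — the analogue
#' of scoring a persistently non-compliant participant as "did not
#' complete" rather than accepting a spurious threshold.
#'
#' @param state A [zest_state()].
#' @param max_trials Trial cap (default `Inf`).
#' @param sd_target Stop when posterior SD (dB) drops to this value or below.
#' @param entropy_target Stop when posterior entropy (nats) drops to this
#'   value or below.
#' @return A list with logicals `stop` and `did_not_complete`.
#' @export
stopping_met <- function(state, max_trials = Inf, sd_target = NULL,
                         entropy_target = NULL) {
  n <- nrow(state$history)
  certain <- TRUE
  if (!is.null(sd_target)) certain <- certain && posterior_sd(state) <= sd_target
  if (!is.null(entropy_target)) {
    certain <- certain && posterior_entropy(state) <= entropy_target
  }
  has_target <- !is.null(sd_target) || !is.null(entropy_target)
  if (has_target && certain) {
    list(stop = TRUE, did_not_complete = FALSE)
  } else if (n >= max_trials) {
    list(stop = TRUE, did_not_complete = has_target)
  } else {
    list(stop = FALSE, did_not_complete = FALSE)
  }
}

#' Simulate one response from a frequency-of-seeing observer
#'
#' Draws a Bernoulli response with probability from the psychometric model;
#' when the observer is in a lapsed attention state the response is
#' additionally suppressed with probability `lapse_inflation`, emulating a
#' missed button press during an attentional lapse.
#'
#' @param truth True threshold, dB.
#' @param model A [psychometric()] object.
#' @param stimulus Stimulus level(s), dB (vectorised).
#' @param lapsed Logical (recycled): is the observer lapsed on each trial?
#' @param lapse_inflation Probability a lapsed trial's response is
#'   suppressed.
#' @return Logical vector of responses. Uses the current RNG stream; seed
#'   upstream for reproducibility.
#' @export
simulate_observer <- function(truth, model, stimulus, lapsed = FALSE,
                              lapse_inflation = 1) {
  n <- length(stimulus)
  lapsed <- rep_len(lapsed, n)
  seen <- runif(n) < p_seen(model, truth, stimulus)
  suppress <- lapsed & (runif(n) < lapse_inflation)
  seen & !suppress
}

#' Run a full (optionally compliance-weighted) ZEST threshold estimate
#'
#' Simulates an adaptive thresholding run against a frequency-of-seeing
#' observer: each trial places a stimulus, draws a response, and performs a
#' compliance-weighted posterior update. With `alpha = 1` throughout this is
#' standard ZEST.
#'
#' @param truth True threshold, dB.
#' @param model Observer/likelihood [psychometric()] model.
#' @param n_trials Maximum number of trials.
#' @param alpha Compliance weights, recycled to `n_trials`.
#' @param lapsed Logical lapse indicator per trial, recycled.
#' @param lapse_inflation Miss-inflation probability on lapsed trials.
#' @param domain,prior Passed to [zest_state()].
#' @param rule Stimulus placement rule, see [select_stimulus()].
#' @param sd_target,entropy_target Optional stopping targets, see
#'   [stopping_met()].
#' @param estimate `"mean"` (default, standard ZEST) or `"mode"`.
#' @return An object of class `zest_fit`: list with `estimate` (dB),
#'   `state`, `trace` (tibble of stimulus/response/alpha/posterior SD) and
#'   `did_not_complete`.
#' @export
run_threshold_estimation <- function(truth, model = psychometric(),
                                     n_trials = 30, alpha = 1, lapsed = FALSE,
                                     lapse_inflation = 1,
                                     domain = seq(0, 40, by = 0.5), prior = NULL,
                                     rule = "posterior_mean",
                                     sd_target = NULL, entropy_target = NULL,
                                     estimate = c("mean", "mode")) {
  estimate <- match.arg(estimate)
  alpha <- rep_len(alpha, n_trials)
  lapsed <- rep_len(lapsed, n_trials)
  state <- zest_state(domain = domain, prior = prior, model = model)
  dnc <- FALSE
  for (i in seq_len(n_trials)) {
    stim <- select_stimulus(state, rule = rule)
    resp <- simulate_observer(truth, model, stim, lapsed[i], lapse_inflation)
    state <- zest_update(state, stim, resp, alpha[i])
    crit <- stopping_met(state, max_trials = n_trials,
                         sd_target = sd_target, entropy_target = entropy_target)
    if (crit$stop) {
      dnc <- crit$did_not_complete
      break
    }
  }
  est <- if (estimate == "mean") posterior_mean(state) else posterior_mode(state)
  structure(
    list(estimate = est, state = state, trace = state$history,
         did_not_complete = dnc, truth = truth),
    class = "zest_fit"
  )
}

#' @export
glance.zest_fit <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate,
    posterior_sd = posterior_sd(x$state),
    n_trials = nrow(x$trace),
    did_not_complete = x$did_not_complete
  )
}

#' @export
tidy.zest_fit <- function(x, ...) {
  dplyr::mutate(x$trace, trial = dplyr::row_number(), .before = 1)
}

#' @export
print.zest_fit <- function(x, ...) {
  cat(sprintf(
    "<zest_fit> estimate %.2f dB after %d trials (posterior SD %.2f dB)%s\n",
    x$estimate, nrow(x$trace), posterior_sd(x$state),
    if (x$did_not_complete) " [did not complete]" else ""
  ))
  invisible(x)
}

#' Map a compliance estimate to a likelihood weight
#'
#' Transforms a raw compliance estimate `theta` (e.g. a composite-biomarker
#' z-score, where larger means *less* compliant) into a weight in `[0, 1]`
#' via a decreasing logistic: `alpha = 1 / (1 + exp(k * (theta - theta0)))`.
#' At `theta = theta0` the weight is 0.5; strongly compliant trials
#' (`theta << theta0`) approach full weight 1 and strongly non-compliant
#' ones approach 0. The logistic shape and its constants are package
#' choices; any monotone map onto `[0, 1]` is admissible.
#'
#' @param theta Raw compliance estimate(s); finite.
#' @param k Steepness (> 0), default 1.5 per z-score unit.
#' @param theta0 Midpoint, default 1 (one SD worse than the cohort mean).
#' @return Weights in `[0, 1]`.
#' @export
alpha_from_compliance <- function(theta, k = 1.5, theta0 = 1) {
  if (any(!is.finite(theta))) abort("theta must be finite.")
  if (!(k > 0)) abort("Steepness k must be > 0.")
  a <- 1 / (1 + exp(k * (theta - theta0)))
  pmin(pmax(a, 0), 1)
}
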