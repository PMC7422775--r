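#' Geometric-mean (reduced major axis) regression
#'
#' The display line used for biomarker-error scatters: slope
#' `sign(r) * sd(y) / sd(x)` with the line passing through the means. Unlike
#' ordinary least squares it treats x and y symmetrically, appropriate when
#' both axes are noisy measurements.
#'
#' @param x,y Numeric vectors.
#' @return A list with `slope` and `intercept`.
#' @examples
#' gm_regression(c(1, 2, 3), c(2, 4, 6))  # slope 2, intercept 0
#' @export
gm_regression <- function(x, y) {
  if (sd(x) == 0) abort("Geometric-mean regression undefined for zero-variance x.")
  r <- cor(x, y)
  slope <- sign(r) * sd(y) / sd(x)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Association between biomarkers and overall test-retest error
#'
#' For each biomarker (averaged across repeat sessions upstream, one value
#' per eye) this computes the Pearson product-moment correlation with the
#' eye's test-retest measurement error, plus a geometric-mean (reduced major
#' axis) regression line for display: slope `sign(r) * sd(y) / sd(x)`,
#' intercept through the means. The correlation-weighted composite
#' ([fit_composite_model()]) is fitted on the same rows and reported
#' alongside the individual biomarkers.
#'
#' Outlier handling is deliberately manual: `exclude` names rows to drop
#' (e.g. a single conspicuous outlier) and every exclusion is logged in the
#' result; there is no automatic outlier detection.
#'
#' @param data One row per eye with biomarker columns and the error column.
#' @param error Name of the measurement-error column (default `"error"`).
#' @param biomarkers Biomarker column names (default: the standard seven
#'   found in `data`).
#' @param exclude Integer row indices (into `data`) to exclude as outliers.
#' @param cohort_label Optional label (e.g. `"healthy"`, `"patient"`)
#'   carried into the result.
#' @return An object of class `vf_association`; `tidy()` gives one row per
#'   biomarker plus `"composite"` with `r`, `p_value`, `slope`, `intercept`,
#'   `n`.
#' @export
testretest_association <- function(data, error = "error",
                                   biomarkers = intersect(biomarker_names(), names(data)),
                                   exclude = NULL, cohort_label = NULL) {
  if (!error %in% names(data)) abort(sprintf("No `%s` column in data.", error))
  excluded <- tibble::tibble()
  if (!is.null(exclude)) {
    excluded <- data[exclude, , drop = FALSE]
    inform(sprintf("Excluding %d row(s) flagged as outliers: %s",
                   length(exclude), paste(exclude, collapse = ", ")))
    data <- data[-exclude, , drop = FALSE]
  }
  if (nrow(data) < 4) abort("Need at least 4 eyes for the association analysis.")
  y_all <- data[[error]]

  assoc_row <- function(x, y, term) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (sd(x) == 0) abort(sprintf("Zero-variance column: %s", term))
    ct <- cor.test(x, y, method = "pearson")
    gm <- gm_regression(x, y)
    tibble::tibble(
      term = term, r = unname(ct$estimate), p_value = ct$p.value,
      slope = gm$slope, intercept = gm$intercept, n = length(x)
    )
  }

  per_bm <- purrr::map_dfr(biomarkers, function(b) assoc_row(data[[b]], y_all, b))
  model <- fit_composite_model(data, target = error, biomarkers = biomarkers)
  complete <- complete.cases(data[biomarkers])
  comp <- rep(NA_real_, nrow(data))
  comp[complete] <- composite_score(model, data[complete, , drop = FALSE])
  res <- dplyr::bind_rows(per_bm, assoc_row(comp[complete], y_all[complete], "composite"))

  structure(
    list(results = res, composite_model = model,
         data = dplyr::mutate(data, composite = comp),
         error = error, excluded = excluded, cohort_label = cohort_label),
    class = "vf_association"
  )
}

#' @export
tidy.vf_association <- function(x, ...) x$results

#' @export
glance.vf_association <- function(x, ...) {
  comp <- dplyr::filter(x$results, .data$term == "composite")
  tibble::tibble(
    cohort = x$cohort_label %||% NA_character_,
    n_eyes = comp$n, composite_r = comp$r, composite_p = comp$p_value,
    n_excluded = nrow(x$excluded)
  )
}

#' @export
print.vf_association <- function(x, ...) {
  cat(sprintf("<vf_association>%s %d eyes, %d excluded\n",
              if (!is.null(x$cohort_label)) paste0(" [", x$cohort_label, "]") else "",
              max(x$results$n), nrow(x$excluded)))
  print(x$results)
  invisible(x)
}

#' Pool per-trial windowed biomarkers and hit/miss outcomes across sessions
#'
#' For every session: extract the clearly visible (suprathreshold) trials
#' ([extract_visible_trials()]), recompute the six video biomarkers on each
#' trial's local window ([windowed_biomarkers()]), and pool everything into
#' one table of (biomarkers, outcome) rows across all eyes. Rows with any
#' missing biomarker (too few valid frames in the window) are dropped and
#' the count logged.
#'
#' @param sessions A list of [vf_session()] objects.
#' @param margin_db Visibility margin, dB (default 3).
#' @param window_frames Preceding frames per trial window (default 20).
#' @return A tibble with `subject_id`, `eye`, `trial`, `hit` (logical),
#'   `outcome`, and the six video biomarker columns.
#' @export
trialwise_dataset <- function(sessions, margin_db = 3, window_frames = 20) {
  if (inherits(sessions, "vf_session")) sessions <- list(sessions)
  rows <- purrr::map_dfr(sessions, function(s) {
    vt <- extract_visible_trials(s, margin_db = margin_db)
    if (nrow(vt) == 0) {
      warn(sprintf("Session %s/%s has no visible trials.", s$subject_id, s$eye))
      return(tibble::tibble())
    }
    wb <- windowed_biomarkers(s, trials = vt$trial, window_frames = window_frames)
    dplyr::bind_cols(
      tibble::tibble(subject_id = s$subject_id, eye = s$eye,
                     trial = vt$trial, outcome = vt$outcome,
                     hit = vt$outcome == "hit"),
      dplyr::select(wb, -"trial")
    )
  })
  if (nrow(rows) == 0) return(rows)
  complete <- complete.cases(rows[video_biomarker_names()])
  if (any(!complete)) {
    inform(sprintf("Dropping %d visible trial(s) with incomplete window biomarkers.",
                   sum(!complete)))
  }
  rows[complete, , drop = FALSE]
}

wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Logistic model of trial-by-trial lapses on a biomarker
#'
#' Fits a binomial logistic regression of the raw binary hit/miss outcome on
#' the raw (untransformed) biomarker value, and tests it against the
#' intercept-only model with a 1-df chi-square (likelihood-ratio) test. For
#' display, hit rates are also summarised in four log-spaced bins spanning
#' the positive biomarker range, with Wilson 95% confidence intervals;
#' zero or negative biomarker values (degenerate inputs) are assigned to the
#' first bin and logged.
#'
#' Complete separation is flagged (no p-value is reported in that case).
#'
#' @param data A table from [trialwise_dataset()] (needs `hit` plus the
#'   biomarker column).
#' @param biomarker Name of the biomarker column to model.
#' @param bins Number of log-spaced bins (default 4).
#' @return An object of class `lapse_model`; `glance()` gives the
#'   chi-square statistic and p-value, `tidy()` the logistic coefficients,
#'   and `$bins` the binned hit-rate summary.
#' @export
fit_lapse_model <- function(data, biomarker, bins = 4) {
  if (!biomarker %in% names(data)) {
    abort(sprintf("No `%s` column in the trialwise table.", biomarker))
  }
  x <- data[[biomarker]]
  y <- data$hit
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (sum(y) < 2 || sum(!y) < 2) {
    abort("Need at least 2 hits and 2 misses to fit the lapse model.")
  }

  separation <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  chisq <- unname(fit$null.deviance - fit$deviance)
  p_value <- if (separation) NA_real_ else pchisq(chisq, df = 1, lower.tail = FALSE)

  pos <- x[x > 0]
  if (length(pos) == 0) abort("All biomarker values are non-positive; cannot bin.")
  edges <- 10^seq(log10(min(pos)), log10(max(pos)), length.out = bins + 1)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  n_degenerate <- sum(x <= 0)
  if (n_degenerate > 0) {
    idx[x <= 0] <- 1L
    inform(sprintf("%d non-positive `%s` value(s) assigned to the first bin.",
                   n_degenerate, biomarker))
  }
  bin_tbl <- dplyr::group_by(tibble::tibble(bin = idx, hit = y), .data$bin)
  bin_tbl <- dplyr::summarise(bin_tbl, n = dplyr::n(), hits = sum(.data$hit),
                              .groups = "drop")
  bin_tbl <- dplyr::mutate(
    bin_tbl,
    lower_edge = edges[.data$bin], upper_edge = edges[.data$bin + 1],
    midpoint = sqrt(.data$lower_edge * .data$upper_edge),
    hit_rate = .data$hits / .data$n,
    wilson_ci(.data$hits, .data$n)
  )

  structure(
    list(biomarker = biomarker, fit = fit, chisq = chisq, p_value = p_value,
         separation = separation, bins = bin_tbl, edges = edges,
         n = length(y), n_degenerate = n_degenerate),
    class = "lapse_model"
  )
}

#' @export
tidy.lapse_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("(Intercept)", x$biomarker),
    estimate = unname(sm[, 1]),
    std_error = unname(sm[, 2]),
    statistic = unname(sm[, 3]),
    p_value = unname(sm[, 4])
  )
}

#' @export
glance.lapse_model <- function(x, ...) {
  tibble::tibble(
    biomarker = x$biomarker, n = x$n,
    slope = unname(coef(x$fit)[2]),
    chisq = x$chisq, p_value = x$p_value, separation = x$separation
  )
}

#' @export
print.lapse_model <- function(x, ...) {
  cat(sprintf(
    "<lapse_model> hit ~ %s on %d visible trials: chisq(1) = %.1f, p = %s%s\n",
    x$biomarker, x$n, x$chisq,
    if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3),
    if (x$separation) " [complete separation]" else ""
  ))
  invisible(x)
}
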