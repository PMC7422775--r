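# Pipeline entry points tying simulate -> biomarkers -> analyze together.
# Each run writes a manifest.json echoing the resolved configuration, seed
# and package version so outputs are traceable.

write_manifest <- function(dir, subcommand, params) {
  manifest <- c(
    list(subcommand = subcommand,
         package = "complimetry",
         version = as.character(utils::packageVersion("complimetry")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    params
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$observer)) raw$observer <- do.call(psychometric, raw$observer)
  bad <- setdiff(names(raw), names(formals(cohort_config)))
  if (length(bad) > 0) {
    abort(sprintf("Unknown generator config field(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(cohort_config, raw)
}

#' Simulate a cohort and write it to disk in the standard CSV dialects
#'
#' Writes one directory per session
#' (`<out_dir>/<subject>/session_<k>/{frames,trials,thresholds}.csv` +
#' `session.json`), a `ground_truth.json` sidecar, the per-eye cohort table,
#' and a manifest.
#'
#' @param out_dir Output directory.
#' @param config A [cohort_config()], a YAML file path of config fields, or
#'   `NULL` for the defaults.
#' @param seed Optional seed overriding the config's.
#' @return The cohort table tibble, invisibly.
#' @export
pipeline_simulate <- function(out_dir, config = NULL, seed = NULL) {
  if (is.character(config)) config <- config_from_yaml(config)
  if (is.null(config)) config <- cohort_config()
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  for (s in seq_along(cohort$subjects)) {
    subj <- cohort$subjects[[s]]
    sid <- subj$sessions[[1]]$subject_id
    for (k in seq_along(subj$sessions)) {
      write_session(subj$sessions[[k]],
                    file.path(out_dir, sid, sprintf("session_%d", k)))
    }
    jsonlite::write_json(
      lapply(subj$truths, function(tr) tr[c("trait", "occupancy", "forced_miss",
                                            "true_thresholds",
                                            "visible_trial_count")]),
      file.path(out_dir, sid, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  readr::write_csv(cohort$cohort, file.path(out_dir, "cohort.csv"), progress = FALSE)
  cfg <- unclass(config)
  cfg$observer <- unclass(cfg$observer)
  write_manifest(out_dir, "simulate", list(config = cfg, seed = config$seed))
  invisible(cohort$cohort)
}

read_cohort_dir <- function(dir, confidence_floor = 0.75) {
  subj_dirs <- list.dirs(dir, recursive = FALSE)
  sessions <- list()
  for (sd in subj_dirs) {
    for (ss in list.dirs(sd, recursive = FALSE)) {
      if (file.exists(file.path(ss, "session.json"))) {
        sessions[[length(sessions) + 1]] <-
          read_session(ss, confidence_floor = confidence_floor)
      }
    }
  }
  if (length(sessions) == 0) abort(sprintf("No sessions found under %s.", dir))
  sessions
}

#' Compute session biomarkers for a set of on-disk sessions
#'
#' Reads each session directory, computes the seven biomarkers, and writes
#' one CSV row per session plus a manifest. Sessions that fail to read are
#' reported and skipped; the run fails only if none can be processed.
#'
#' @param session_dirs Session directories (or one cohort directory as
#'   written by [pipeline_simulate()]).
#' @param out_dir Output directory for `biomarkers.csv` and the manifest.
#' @param confidence_floor Frame-validity confidence floor.
#' @return The biomarker tibble, invisibly.
#' @export
pipeline_biomarkers <- function(session_dirs, out_dir,
                                confidence_floor = 0.75) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (length(session_dirs) == 1 &&
      !file.exists(file.path(session_dirs, "session.json"))) {
    sessions <- read_cohort_dir(session_dirs, confidence_floor)
  } else {
    sessions <- list()
    for (d in session_dirs) {
      sessions[[length(sessions) + 1]] <- tryCatch(
        read_session(d, confidence_floor = confidence_floor),
        error = function(e) {
          warn(sprintf("Skipping unreadable session %s: %s", d, conditionMessage(e)))
          NULL
        }
      )
    }
    sessions <- Filter(Negate(is.null), sessions)
    if (length(sessions) == 0) abort("No readable sessions.")
  }
  bm <- purrr::map_dfr(sessions, session_biomarkers)
  validity <- vapply(sessions, function(s) mean(s$frames$valid), numeric(1))
  inform(sprintf("Processed %d session(s); mean frame validity %.1f%%.",
                 length(sessions), 100 * mean(validity)))
  readr::write_csv(bm, file.path(out_dir, "biomarkers.csv"), progress = FALSE)
  write_manifest(out_dir, "biomarkers",
                 list(n_sessions = length(sessions),
                      confidence_floor = confidence_floor))
  invisible(bm)
}

#' Run the test-retest or trialwise analysis on an on-disk cohort
#'
#' `mode = "testretest"`: per-eye biomarkers are mean-averaged across the
#' repeat sessions, measurement error is the absolute MS difference, and
#' [testretest_association()] is run; results JSON and the association
#' figure are written. `mode = "trialwise"`: visible trials are pooled
#' across all sessions ([trialwise_dataset()]) and a [fit_lapse_model()] is
#' fitted per video biomarker, with one binned-hit-rate figure each.
#'
#' @param cohort_dir A directory written by [pipeline_simulate()].
#' @param out_dir Output directory.
#' @param mode `"testretest"` or `"trialwise"`.
#' @param margin_db,window_frames,bins Analysis parameters.
#' @param seed Recorded in the manifest (the analysis itself is
#'   deterministic given the data).
#' @param plots Write figure PNGs (default `TRUE`).
#' @return The fitted result object(s), invisibly.
#' @export
pipeline_analyze <- function(cohort_dir, out_dir,
                             mode = c("testretest", "trialwise"),
                             margin_db = 3, window_frames = 20, bins = 4,
                             seed = NULL, plots = TRUE) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- read_cohort_dir(cohort_dir)

  if (mode == "testretest") {
    bm <- purrr::map_dfr(sessions, session_biomarkers)
    per_eye <- dplyr::summarise(
      dplyr::group_by(bm, .data$subject_id, .data$eye),
      dplyr::across(dplyr::all_of(biomarker_names()), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
    ms <- purrr::map_dfr(sessions, function(s) tibble::tibble(
      subject_id = s$subject_id, eye = s$eye,
      ms = mean_sensitivity(s$thresholds)
    ))
    err <- dplyr::summarise(
      dplyr::group_by(ms, .data$subject_id, .data$eye),
      error = if (dplyr::n() >= 2) test_retest_error(.data$ms[1], .data$ms[2])
              else NA_real_,
      .groups = "drop"
    )
    tbl <- dplyr::inner_join(per_eye, err, by = c("subject_id", "eye"))
    tbl <- dplyr::filter(tbl, !is.na(.data$error))
    if (nrow(tbl) < 4) {
      abort("Test-retest analysis needs at least 4 eyes with two sessions each.")
    }
    res <- testretest_association(tbl)
    jsonlite::write_json(
      list(mode = "testretest", results = tidy(res),
           composite_model = unclass(res$composite_model)),
      file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA
    )
    if (plots) {
      ggplot2::ggsave(file.path(out_dir, "association.png"), autoplot(res),
                      width = 9, height = 7, dpi = 150)
    }
    out <- res
  } else {
    tw <- trialwise_dataset(sessions, margin_db = margin_db,
                            window_frames = window_frames)
    if (nrow(tw) == 0) abort("No visible trials in the cohort; cannot analyze.")
    fits <- lapply(video_biomarker_names(), function(b) {
      fit_lapse_model(tw, b, bins = bins)
    })
    names(fits) <- video_biomarker_names()
    jsonlite::write_json(
      list(mode = "trialwise", n_trials = nrow(tw),
           models = purrr::map_dfr(fits, glance)),
      file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA
    )
    if (plots) {
      for (b in names(fits)) {
        ggplot2::ggsave(file.path(out_dir, paste0("lapse_", b, ".png")),
                        autoplot(fits[[b]]), width = 5, height = 4, dpi = 150)
      }
    }
    out <- fits
  }
  write_manifest(out_dir, paste0("analyze-", mode),
                 list(cohort_dir = cohort_dir, margin_db = margin_db,
                      window_frames = window_frames, bins = bins, seed = seed))
  invisible(out)
}

#' Compare compliance-weighted against naive ZEST by paired simulation
#'
#' Runs paired replicates of a thresholding simulation in which the observer
#' lapses (response suppressed) on a fraction of trials. The naive run
#' weights every trial fully (`alpha = 1`); the informed run sets
#' `alpha = 0` on exactly the lapsed trials. Reports the paired RMSE of the
#' two final estimates against the true threshold.
#'
#' @param n_reps Number of paired replicates (default 200).
#' @param truth True threshold, dB.
#' @param lapse_rate Fraction of lapsed trials (default 0.3).
#' @param n_trials Trials per run (default 30).
#' @param model Observer [psychometric()] model.
#' @param seed Base seed.
#' @return A tibble with one row per arm: `arm`, `rmse`, `bias`, `n_reps`.
#' @export
pipeline_zest_demo <- function(n_reps = 200, truth = 25, lapse_rate = 0.3,
                               n_trials = 30, model = psychometric(), seed = 1) {
  est <- matrix(NA_real_, n_reps, 2, dimnames = list(NULL, c("naive", "weighted")))
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    lapsed <- runif(n_trials) < lapse_rate
    set.seed(seed + r + 500000L)
    naive <- run_threshold_estimation(truth, model, n_trials = n_trials,
                                      alpha = 1, lapsed = lapsed)
    set.seed(seed + r + 500000L)
    informed <- run_threshold_estimation(truth, model, n_trials = n_trials,
                                         alpha = ifelse(lapsed, 0, 1),
                                         lapsed = lapsed)
    est[r, ] <- c(naive$estimate, informed$estimate)
  }
  tibble::tibble(
    arm = c("naive", "weighted"),
    rmse = apply(est, 2, function(e) sqrt(mean((e - truth)^2))),
    bias = apply(est, 2, function(e) mean(e - truth)),
    n_reps = n_reps
  )
}
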