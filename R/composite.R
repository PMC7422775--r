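#' Fit the correlation-weighted composite biomarker
#'
#' The composite is a deliberately simple combination rule chosen to avoid
#' overfitting small cohorts: each biomarker column is standardised to a
#' z-score against the analysis cohort (sample mean and SD, denominator
#' n - 1), and the composite is the weighted linear sum of the z-scores with
#' weights proportional to each biomarker's Pearson correlation with the
#' target (typically test-retest measurement error), normalised to sum to
#' one:
#' \deqn{\omega_i = \rho_i / \sum_j \rho_j.}
#' Correlations keep their sign; if they sum to a non-positive value the
#' weights are undefined and an error is raised.
#'
#' @param data A data frame with one row per eye and the biomarker columns.
#' @param target Name of the target column (e.g. `"error"`), or a numeric
#'   vector of length `nrow(data)`.
#' @param biomarkers Character vector of biomarker column names (default:
#'   the seven standard biomarkers present in `data`).
#' @return An object of class `composite_model` with per-biomarker
#'   standardisation means/SDs, correlations `rho` and weights `omega`.
#' @export
fit_composite_model <- function(data, target = "error",
                                biomarkers = intersect(biomarker_names(), names(data))) {
  y <- if (is.character(target)) data[[target]] else as.numeric(target)
  if (is.null(y)) abort("Target column not found in `data`.")
  if (length(biomarkers) == 0) abort("No biomarker columns to combine.")
  keep <- complete.cases(data[biomarkers]) & !is.na(y)
  x <- data[keep, biomarkers, drop = FALSE]
  y <- y[keep]
  if (nrow(x) < 3) abort("Need at least 3 complete sessions to fit the composite.")
  sds <- vapply(x, sd, numeric(1))
  zero_var <- names(sds)[sds == 0]
  if (length(zero_var) > 0) {
    abort(sprintf("Biomarker(s) with zero variance cannot be standardised: %s",
                  paste(zero_var, collapse = ", ")))
  }
  mus <- vapply(x, mean, numeric(1))
  rho <- vapply(x, function(col) cor(col, y), numeric(1))
  if (sum(rho) <= 0) {
    abort(sprintf(
      "Degenerate composite weights: correlations sum to %.3f <= 0.", sum(rho)
    ))
  }
  structure(
    list(biomarkers = biomarkers, mean = mus, sd = sds,
         rho = rho, omega = rho / sum(rho), n = nrow(x), c_n = 1),
    class = "composite_model"
  )
}

#' Score sessions with a fitted composite model
#'
#' Computes `sum_i omega_i * (X_i - mean_i) / sd_i` per row. A missing
#' biomarker with a nonzero weight is an error — the composite is undefined
#' there.
#'
#' @param model A [fit_composite_model()] object.
#' @param data Data frame with the model's biomarker columns (or a one-row
#'   biomarker tibble from [session_biomarkers()]).
#' @return Numeric composite scores (z units), one per row.
#' @export
composite_score <- function(model, data) {
  stopifnot(inherits(model, "composite_model"))
  missing_cols <- setdiff(model$biomarkers, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Data lack biomarker column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  x <- as.matrix(data[model$biomarkers])
  weighted_na <- is.na(x) & rep(model$omega != 0, each = nrow(x))
  if (any(weighted_na)) {
    abort("Missing biomarker value(s) with nonzero composite weight.")
  }
  z <- sweep(sweep(x, 2, model$mean, "-"), 2, model$sd, "/")
  z[is.na(z)] <- 0  # only reachable for zero-weight columns
  as.numeric(z %*% model$omega)
}

#' @export
predict.composite_model <- function(object, newdata, ...) {
  composite_score(object, newdata)
}

#' @export
tidy.composite_model <- function(x, ...) {
  tibble::tibble(
    biomarker = x$biomarkers,
    mean = unname(x$mean),
    sd = unname(x$sd),
    rho = unname(x$rho),
    weight = unname(x$omega)
  )
}

#' @export
glance.composite_model <- function(x, ...) {
  tibble::tibble(n = x$n, sum_rho = sum(x$rho), n_biomarkers = length(x$biomarkers))
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("<composite_model> %d biomarkers fitted on %d sessions\n",
              length(x$biomarkers), x$n))
  print(tidy(x))
  invisible(x)
}

#' Serialise / restore a composite model as JSON
#'
#' @param model A `composite_model`.
#' @param path JSON file path.
#' @return `composite_to_json()` the path invisibly; `composite_from_json()`
#'   the restored model.
#' @export
composite_to_json <- function(model, path) {
  stopifnot(inherits(model, "composite_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname composite_to_json
#' @export
composite_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("mean", "sd", "rho", "omega")) {
    obj[[f]] <- setNames(as.numeric(obj[[f]]), obj$biomarkers)
  }
  structure(obj, class = "composite_model")
}
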