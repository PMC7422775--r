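#' Plot biomarker-error associations
#'
#' Scatter of measurement error against each biomarker (and the composite),
#' with the geometric-mean regression line overlaid — one panel per term.
#'
#' @param object A [testretest_association()] result.
#' @param terms Terms to plot (default: all, composite included).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vf_association <- function(object, terms = object$results$term, ...) {
  dat <- object$data
  long <- tidyr::pivot_longer(
    dplyr::select(dat, dplyr::all_of(c(object$error, intersect(terms, names(dat))))),
    cols = -dplyr::all_of(object$error),
    names_to = "term", values_to = "value"
  )
  lines <- dplyr::filter(object$results, .data$term %in% !!terms)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data[[object$error]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept)
    ) +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "biomarker value", y = "measurement error (dB)",
                  title = "Compliance biomarkers vs test-retest error") +
    ggplot2::theme_minimal()
}

#' Plot a trial-by-trial lapse model
#'
#' Binned hit rates (Wilson 95% CIs) on a log biomarker axis with the fitted
#' logistic curve from the raw binary data.
#'
#' @param object A [fit_lapse_model()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lapse_model <- function(object, ...) {
  rng <- range(object$edges)
  grid <- tibble::tibble(x = exp(seq(log(rng[1]), log(rng[2]), length.out = 200)))
  grid$p <- predict(object$fit, newdata = data.frame(x = grid$x), type = "response")
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$midpoint, y = .data$hit_rate)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$x, y = .data$p),
                       inherit.aes = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.05) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = object$biomarker, y = "P(hit) on visible trials",
      title = sprintf("Lapse prediction: hit ~ %s (chisq p = %s)",
                      object$biomarker,
                      if (is.na(object$p_value)) "NA"
                      else format.pval(object$p_value, digits = 2))
    ) +
    ggplot2::theme_minimal()
}
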