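#' Robust Sn dispersion of a point cloud
#'
#' Rousseeuw and Croux's Sn statistic generalised to d-dimensional points:
#' the median over points of the median Euclidean distance to every other
#' point,
#' \deqn{S_n = c_n \, \mathrm{med}_i \; \mathrm{med}_{j \neq i} \; \|p_i - p_j\|.}
#' The finite-sample bias factor \eqn{c_n} is taken as 1. Sn is highly
#' robust (50\% breakdown in one dimension) and makes no normality
#' assumption, which is why it is used here to summarise gaze and head-pose
#' scatter: a handful of tracking glitches should not dominate a session's
#' variability score.
#'
#' Medians use the usual convention: the mean of the two central order
#' statistics when the count is even. The inner median for point i is over
#' the n - 1 distances to the other points.
#'
#' @param x A numeric matrix (rows = points, columns = dimensions), a data
#'   frame of numeric columns, or a plain numeric vector (treated as
#'   one-dimensional points).
#' @return A single non-negative number, or `NA_real_` when fewer than two
#'   points are supplied (insufficient data).
#' @examples
#' sn_dispersion(c(0, 1, 2))              # 1.5
#' sn_dispersion(rbind(c(0, 0), c(3, 4))) # 5
#' @export
sn_dispersion <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 2) return(NA_real_)
  if (!all(is.finite(x))) {
    abort("sn_dispersion() requires all coordinates to be finite.")
  }
  d <- as.matrix(stats::dist(x))
  inner <- vapply(seq_len(n), function(i) median(d[i, -i]), numeric(1))
  median(inner)
}
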