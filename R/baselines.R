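# Classical estimators: Pearson correlation on (averaged) scores, Fisher
# z-transform intervals, and the analytic attenuation coefficient that
# predicts how trial noise biases the averaging estimator.

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @return The sample correlation.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation is undefined")
  cor(x, y)
}

#' Fisher z-transform confidence interval for a correlation
#'
#' `tanh(atanh(r) +/- z_{alpha/2} / sqrt(n - 3))`.
#'
#' @param r Sample correlation.
#' @param n Number of paired observations (> 3).
#' @param level Confidence level (default .95).
#' @return A tibble with `estimate`, `conf.low`, `conf.high`, `n`, `level`.
#'   `|r| = 1` returns the degenerate interval `[r, r]` with a warning.
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (n <= 3) stop("Fisher interval requires n > 3")
  if (abs(r) > 1) stop("r must lie in [-1, 1]")
  if (abs(r) == 1) {
    warning("|r| = 1: returning a degenerate interval")
    return(tibble::tibble(estimate = r, conf.low = r, conf.high = r,
                          n = as.integer(n), level = level))
  }
  zc <- qnorm(1 - (1 - level) / 2)
  half <- zc / sqrt(n - 3)
  tibble::tibble(estimate = r,
                 conf.low = tanh(atanh(r) - half),
                 conf.high = tanh(atanh(r) + half),
                 n = as.integer(n), level = level)
}

#' The averaging estimator: per-cell means, then correlate
#'
#' Collapses trial-level data to individual-by-task scores (cell means; for
#' contrast designs, the per-individual difference between the `x = +.5` and
#' `x = -.5` condition means) and returns the Pearson correlation with its
#' Fisher interval for one task pair. This is the conventional analysis whose
#' estimate is attenuated by trial noise.
#'
#' @param data A trial tibble (columns `individual`, `task`, `score`, and
#'   `condition` for contrast designs).
#' @param tasks Length-2 integer vector: which task pair to correlate.
#' @param level Confidence level.
#' @return A one-row tibble: `method`, `term`, `estimate`, `conf.low`,
#'   `conf.high`, `n`.
#' @export
average_then_correlate <- function(data, tasks = c(1L, 2L), level = 0.95) {
  stopifnot(length(tasks) == 2L)
  scores <- averaged_scores(data)
  x <- scores[, tasks[1L]]
  y <- scores[, tasks[2L]]
  r <- pearson(x, y)
  ci <- fisher_ci(r, length(x), level)
  tibble::tibble(method = "average",
                 term = rho_name(min(tasks), max(tasks)),
                 estimate = r, conf.low = ci$conf.low, conf.high = ci$conf.high,
                 n = length(x))
}

# individual x task matrix of averaged scores (mean difference across the
# two conditions for contrast data)
averaged_scores <- function(data) {
  data <- as_tibble(data)
  if ("condition" %in% names(data) && !all(is.na(data$condition))) {
    cells <- data |>
      group_by(.data$individual, .data$task, .data$condition) |>
      summarise(m = mean(.data$score), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "m",
                         names_prefix = "c") |>
      mutate(value = .data$c2 - .data$c1)
  } else {
    cells <- data |>
      group_by(.data$individual, .data$task) |>
      summarise(value = mean(.data$score), .groups = "drop")
  }
  wide <- tidyr::pivot_wider(cells[, c("individual", "task", "value")],
                             names_from = "task", values_from = "value")
  wide <- arrange(wide, .data$individual)
  as.matrix(wide[, -1L, drop = FALSE])
}

#' Analytic attenuation coefficient
#'
#' The multiplicative bias of the correlation of error-perturbed scores:
#' `sigma_1 sigma_2 / sqrt((sigma_1^2 + tau_1^2 / L)(sigma_2^2 + tau_2^2 / L))`.
#' With `L = 1` this is the attenuation of raw observed scores; with the
#' number of averaged trials `L` it predicts the expected correlation of the
#' averaging estimator, `E(r) ~ factor * rho`.
#'
#' @param sigma Length-2 vector of true between-individual SDs (> 0).
#' @param tau Length-2 vector of trial-noise SDs (>= 0).
#' @param L Number of trials averaged per cell (>= 1).
#' @return The attenuation factor in (0, 1].
#' @export
attenuation_coefficient <- function(sigma, tau, L = 1) {
  sigma <- rep_len(sigma, 2L); tau <- rep_len(tau, 2L)
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(tau < 0) || L < 1) stop("tau must be nonnegative and L >= 1")
  sigma[1] * sigma[2] /
    sqrt((sigma[1]^2 + tau[1]^2 / L) * (sigma[2]^2 + tau[2]^2 / L))
}
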