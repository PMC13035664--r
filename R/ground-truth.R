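#' Generative ground truth for a simulated multi-task experiment
#'
#' A `ground_truth` object is the complete specification of one synthetic
#' study: the number of individuals `I`, tasks `J`, and replicate trials `L`,
#' the task means `mu`, the between-individual standard deviations `sigma`,
#' the true correlation matrix `rho`, and the trial-noise standard deviations
#' `tau`. For contrast designs it additionally carries the intercept
#' distribution and the two contrast codes.
#'
#' Presets encode the standard study conditions:
#' * `"two_task"`: J = 2, `mu = (.5, .5)`, `sigma = (.1, .1)`, I = 200,
#'   L = 20, a single free correlation (default .5) and trial noise
#'   (default .2).
#' * `"four_task"`: the two-factor pattern with `rho12 = .3`, `rho13 = .5`,
#'   `rho14 = .7`; the remaining entries are completed as `rho23 = .3`,
#'   `rho24 = .5`, `rho34 = .3` (a documented positive-definite completion;
#'   only the three labeled coefficients are pinned by design).
#' * `"eight_task"`: `rho12 = .8` with all other off-diagonals .2.
#' * `"contrast"`: two tasks of two conditions each; intercepts
#'   `Normal(600, 100^2)` ms, slope means 60 ms, slope SDs 25 ms, slope
#'   correlation .5, `tau = 175` ms, L = 150 trials per condition.
#'
#' @param preset One of `"two_task"`, `"four_task"`, `"eight_task"`,
#'   `"contrast"`.
#' @param rho For `"two_task"` (and `"eight_task"`) a scalar in (-1, 1)
#'   replacing the focal correlation, or a full J x J correlation matrix for
#'   any preset.
#' @param tau Scalar or length-J vector of trial-noise SDs (score units).
#' @param I,L Number of individuals and trials per cell (contrast designs:
#'   trials per individual x task x condition).
#' @param mu,sigma Optional overrides for the task means and
#'   between-individual SDs.
#' @param design One of `"hierarchical"`, `"manifest"`, `"contrast"`;
#'   defaults to `"contrast"` for the contrast preset and `"hierarchical"`
#'   otherwise.
#' @param intercept_mean,intercept_sd Intercept distribution for contrast
#'   designs (ms).
#' @param contrast_codes Length-2 contrast codes, fixed at `c(-.5, .5)`.
#'
#' @return An object of class `ground_truth`.
#' @export
#' @examples
#' make_ground_truth("two_task", rho = .3, tau = .2)
#' make_ground_truth("contrast")
make_ground_truth <- function(preset = c("two_task", "four_task", "eight_task", "contrast"),
                              rho = NULL, tau = NULL, I = 200L, L = NULL,
                              mu = NULL, sigma = NULL, design = NULL,
                              intercept_mean = 600, intercept_sd = 100,
                              contrast_codes = c(-0.5, 0.5)) {
  if (is.character(preset) && length(preset) == 1L &&
      !preset %in% c("two_task", "four_task", "eight_task", "contrast")) {
    stop("unknown preset '", preset, "'; use one of two_task, four_task, eight_task, contrast")
  }
  preset <- match.arg(preset)

  spec <- switch(preset,
    two_task = list(J = 2L, mu = c(.5, .5), sigma = c(.1, .1), tau = .2, L = 20L,
                    rho_default = .5, units = "score"),
    four_task = list(J = 4L, mu = rep(.5, 4), sigma = rep(.1, 4), tau = .2, L = 20L,
                     rho_default = NA, units = "score"),
    eight_task = list(J = 8L, mu = rep(.5, 8), sigma = rep(.1, 8), tau = .4, L = 20L,
                      rho_default = .8, units = "score"),
    contrast = list(J = 2L, mu = c(60, 60), sigma = c(25, 25), tau = 175, L = 150L,
                    rho_default = .5, units = "ms")
  )
  J <- spec$J

  rho_mat <- preset_rho(preset, J, rho, spec$rho_default)
  mu <- if (is.null(mu)) spec$mu else rep_len(as.numeric(mu), J)
  sigma <- if (is.null(sigma)) spec$sigma else rep_len(as.numeric(sigma), J)
  tau <- if (is.null(tau)) rep_len(spec$tau, J) else rep_len(as.numeric(tau), J)
  L <- if (is.null(L)) spec$L else as.integer(L)
  design <- design %||% if (preset == "contrast") "contrast" else "hierarchical"
  design <- match.arg(design, c("hierarchical", "manifest", "contrast"))

  gt <- structure(
    list(preset = preset, design = design, I = as.integer(I), J = J, L = L,
         mu = mu, sigma = sigma, rho = rho_mat, tau = tau,
         units = spec$units,
         intercept_mean = if (design == "contrast") intercept_mean else NULL,
         intercept_sd = if (design == "contrast") intercept_sd else NULL,
         contrast_codes = if (design == "contrast") contrast_codes else NULL),
    class = "ground_truth"
  )
  validate_ground_truth(gt)
}

preset_rho <- function(preset, J, rho, rho_default) {
  if (is.matrix(rho)) {
    if (!all(dim(rho) == c(J, J))) stop("rho matrix must be ", J, " x ", J)
    return(rho)
  }
  if (!is.null(rho) && (!is.numeric(rho) || length(rho) != 1L)) {
    stop("rho must be a scalar or a full correlation matrix")
  }
  if (!is.null(rho) && abs(rho) >= 1) stop("requested correlations must lie in (-1, 1)")
  switch(preset,
    two_task = {
      r <- rho %||% rho_default
      matrix(c(1, r, r, 1), 2L, 2L)
    },
    four_task = {
      if (!is.null(rho)) stop("the four_task preset is completed from its fixed pattern; ",
                              "override with a full 4 x 4 matrix instead of a scalar")
      m <- diag(4)
      m[1, 2] <- .3; m[1, 3] <- .5; m[1, 4] <- .7
      m[2, 3] <- .3; m[2, 4] <- .5; m[3, 4] <- .3
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    },
    eight_task = {
      r <- rho %||% rho_default
      m <- matrix(.2, 8L, 8L); diag(m) <- 1
      m[1, 2] <- m[2, 1] <- r
      m
    },
    contrast = {
      r <- rho %||% rho_default
      matrix(c(1, r, r, 1), 2L, 2L)
    }
  )
}

#' Synthetic manifest-study ground truth
#'
#' Builds a manifest-design ground truth emulating a battery of correlated
#' body-metric style measurements: a `J`-variable multivariate normal with a
#' focal pair correlation (`rho_pair`, variables 1 and 2) against a common
#' background correlation. Used as the synthetic stand-in for the
#' anthropometric manifest study (10 variables, samples of 200).
#'
#' @param J Number of variables (>= 2).
#' @param rho_pair Correlation between variables 1 and 2.
#' @param rho_background Correlation among all other pairs.
#' @param I Number of individuals.
#' @param mu,sigma Mean and SD, recycled to length `J`.
#' @return A `ground_truth` with `design = "manifest"`.
#' @export
make_manifest_truth <- function(J = 10L, rho_pair = .5, rho_background = .3,
                                I = 200L, mu = 0, sigma = 1) {
  rho <- matrix(rho_background, J, J); diag(rho) <- 1
  rho[1, 2] <- rho[2, 1] <- rho_pair
  gt <- structure(
    list(preset = "manifest", design = "manifest", I = as.integer(I), J = as.integer(J),
         L = 1L, mu = rep_len(as.numeric(mu), J), sigma = rep_len(as.numeric(sigma), J),
         rho = rho, tau = rep(0, J), units = "score",
         intercept_mean = NULL, intercept_sd = NULL, contrast_codes = NULL),
    class = "ground_truth"
  )
  validate_ground_truth(gt)
}

#' Validate a ground-truth object
#'
#' Checks symmetry, unit diagonal, and positive semidefiniteness (to
#' tolerance -1e-10 on the smallest eigenvalue) of the correlation matrix,
#' nonnegativity of all SDs, and the contrast codes.
#'
#' @param gt A `ground_truth`.
#' @return `gt`, invisibly on success; errors otherwise.
#' @export
validate_ground_truth <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  if (gt$I < 1L || gt$J < 1L || gt$L < 1L) stop("I, J, and L must be positive")
  rho <- gt$rho
  if (!isTRUE(all.equal(rho, t(rho), tolerance = 1e-12))) stop("rho must be symmetric")
  if (max(abs(diag(rho) - 1)) > 1e-12) stop("rho must have unit diagonal")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop(sprintf("correlation matrix is not positive semidefinite (smallest eigenvalue %.3e)",
                 min(ev)))
  }
  if (any(gt$sigma < 0)) stop("sigma entries must be nonnegative")
  if (any(gt$tau < 0)) stop("tau entries must be nonnegative")
  if (length(gt$mu) != gt$J || length(gt$sigma) != gt$J || length(gt$tau) != gt$J) {
    stop("mu, sigma, tau must all have length J")
  }
  if (identical(gt$design, "contrast")) {
    if (!setequal(gt$contrast_codes, c(-0.5, 0.5))) {
      stop("contrast codes must be -0.5 and 0.5")
    }
  }
  invisible(gt)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> preset '%s' (%s design)\n", x$preset, x$design))
  cat(sprintf("  I = %d individuals, J = %d tasks, L = %d trials/cell (%s units)\n",
              x$I, x$J, x$L, x$units))
  cat("  mu    =", paste(signif(x$mu, 4), collapse = ", "), "\n")
  cat("  sigma =", paste(signif(x$sigma, 4), collapse = ", "), "\n")
  cat("  tau   =", paste(signif(x$tau, 4), collapse = ", "), "\n")
  off <- x$rho[upper.tri(x$rho)]
  cat("  rho (upper tri) =", paste(signif(off, 3), collapse = ", "), "\n")
  if (identical(x$design, "contrast")) {
    cat(sprintf("  intercepts ~ Normal(%g, %g^2), codes %s\n",
                x$intercept_mean, x$intercept_sd,
                paste(x$contrast_codes, collapse = "/")))
  }
  invisible(x)
}

#' Covariance matrix implied by a ground truth
#' @param gt A `ground_truth`.
#' @return The J x J covariance `D(sigma) rho D(sigma)`.
#' @export
true_cov <- function(gt) {
  diag(gt$sigma, gt$J) %*% gt$rho %*% diag(gt$sigma, gt$J)
}

#' Serialize / restore a ground truth as JSON
#'
#' @param gt A `ground_truth`.
#' @param path File path.
#' @return `read_ground_truth()` returns the restored `ground_truth`;
#'   `write_ground_truth()` returns `path` invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  validate_ground_truth(gt)
  out <- gt
  out$rho <- unclass(out$rho)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt <- structure(list(
    preset = raw$preset, design = raw$design, I = as.integer(raw$I),
    J = as.integer(raw$J), L = as.integer(raw$L),
    mu = as.numeric(raw$mu), sigma = as.numeric(raw$sigma),
    rho = matrix(as.numeric(raw$rho), raw$J, raw$J),
    tau = as.numeric(raw$tau), units = raw$units,
    intercept_mean = raw$intercept_mean, intercept_sd = raw$intercept_sd,
    contrast_codes = if (is.null(raw$contrast_codes)) NULL else as.numeric(raw$contrast_codes)),
    class = "ground_truth")
  validate_ground_truth(gt)
}
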