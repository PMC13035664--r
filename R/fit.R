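# Posterior inference wrappers: data reduction to per-cell sufficient
# statistics, chain configuration, and the corr_fit result container.

#' MCMC chain configuration
#'
#' @param n_burn Burn-in iterations (default 1000).
#' @param n_keep Retained iterations per chain (default 3000).
#' @param n_chains Number of chains (default 1; use 4 for diagnostic runs).
#' @param seed Integer seed; chain `c` is run under `seed + c - 1`. `NULL`
#'   leaves the current RNG stream untouched.
#' @param target_accept Target acceptance rate for the LKJ Metropolis blocks
#'   (Robbins-Monro adaptation during burn-in only).
#' @return A `chain_config` list.
#' @export
chain_config <- function(n_burn = 1000L, n_keep = 3000L, n_chains = 1L,
                         seed = NULL, target_accept = 0.30) {
  if (n_burn <= 0 || n_keep <= 0) stop("n_burn and n_keep must be positive")
  structure(list(n_burn = as.integer(n_burn), n_keep = as.integer(n_keep),
                 n_chains = as.integer(n_chains), seed = seed,
                 target_accept = target_accept),
            class = "chain_config")
}

# reduce long trial data to per-cell sufficient statistics (cell means,
# within-cell sums of squares, counts); base rowsum keeps this cheap inside
# replicate sweeps
prepare_hier_data <- function(data) {
  req <- c("individual", "task", "score")
  if (!all(req %in% names(data))) {
    stop("trial data needs columns ", paste(req, collapse = ", "))
  }
  if (any(!is.finite(data$score))) stop("scores must be finite")
  I <- max(data$individual); J <- max(data$task)
  if (!setequal(unique(data$individual), seq_len(I)) ||
      !setequal(unique(data$task), seq_len(J))) {
    stop("individual and task ids must be dense and 1-based")
  }
  key <- (data$task - 1L) * I + data$individual
  cnt <- tabulate(key, I * J)
  if (any(cnt == 0L)) stop("every individual x task cell must be nonempty")
  s1 <- rowsum(data$score, key)
  s2 <- rowsum(data$score^2, key)
  m <- matrix(s1 / cnt, I, J)
  list(I = I, J = J, m = m,
       neff = matrix(as.double(cnt), I, J),
       ssw = matrix(pmax(s2 - s1^2 / cnt, 0), I, J),
       ntrials = colSums(matrix(cnt, I, J)),
       u = sd(data$score))
}

prepare_contrast_data <- function(data) {
  if (!"condition" %in% names(data)) {
    stop("contrast designs need a condition column with values 1 and 2")
  }
  if (!setequal(unique(data$condition), 1:2)) {
    stop("contrast designs need exactly 2 conditions (coded 1 and 2)")
  }
  if (any(!is.finite(data$score))) stop("scores must be finite")
  I <- max(data$individual); J <- max(data$task)
  key <- ((data$condition - 1L) * J + (data$task - 1L)) * I + data$individual
  cnt <- tabulate(key, 2L * I * J)
  if (any(cnt == 0L)) stop("every individual x task x condition cell must be nonempty")
  half <- I * J
  if (any(cnt[seq_len(half)] != cnt[half + seq_len(half)])) {
    stop("unbalanced condition counts within a cell are not supported")
  }
  s1 <- rowsum(data$score, key)
  s2 <- rowsum(data$score^2, key)
  mcell <- s1 / cnt
  sscell <- pmax(s2 - s1^2 / cnt, 0)
  m1 <- matrix(mcell[seq_len(half)], I, J)          # condition 1 (x = -.5)
  m2 <- matrix(mcell[half + seq_len(half)], I, J)   # condition 2 (x = +.5)
  n1 <- matrix(as.double(cnt[seq_len(half)]), I, J)
  list(I = I, J = J,
       m = m2 - m1,                 # per-cell contrast estimate
       abar = (m1 + m2) / 2,        # per-cell intercept estimate
       neff = n1 / 2,               # effective count for the slope
       ncond = n1,
       ssw = matrix(sscell[seq_len(half)] + sscell[half + seq_len(half)], I, J),
       ntrials = colSums(2 * n1),
       u = sd(data$score))
}

default_init <- function(stats, J, likelihood, jitter = TRUE) {
  if (!likelihood) {
    return(list(theta = matrix(0, max(stats$I, 1L), J), mu = rep(0, J),
                tau2 = rep(1, J), Sigma = diag(J)))
  }
  m <- stats$m
  Sigma0 <- cov(m) + diag(1e-6 * max(diag(cov(m)), 1e-12) + 1e-12, J)
  tau20 <- if (is.null(stats$ssw)) rep(1, J) else {
    pmax(colSums(stats$ssw) / pmax(stats$ntrials - stats$I, 1), 1e-10)
  }
  mu0 <- colMeans(m)
  if (jitter) {
    mu0 <- mu0 + rnorm(J, 0, apply(m, 2, sd) / sqrt(stats$I))
    tau20 <- tau20 * exp(rnorm(J, 0, 0.1))
  }
  list(theta = m, mu = mu0, tau2 = tau20, Sigma = Sigma0)
}

run_chains <- function(stats, rp, config, design, likelihood, store_theta,
                       fix_mu = NULL) {
  J <- stats$J
  u <- if (likelihood) stats$u else 1
  mu_prior_var <- rep((100 * u)^2, J)
  tau_b <- rep(0.01 * u^2, J)
  alpha_prior_var <- rep((100 * u)^2, J)
  prior_type <- match(rp$family, c("iw", "siw", "lkj")) - 1L
  S_iw <- if (rp$family == "iw") rp$S else diag(J)
  s_vec <- if (rp$family == "iw") rep(1, J) else rp$s
  v_or_eta <- switch(rp$family, iw = rp$v, siw = rp$v, lkj = rp$eta)
  fam <- if (rp$family == "lkj") rep(rp$fam_id, J) else rep(1L, J)
  fam_par <- if (rp$family == "lkj") rp$fam_par else cbind(rep(2, J), rep(1, J))
  abar <- stats$abar %||% matrix(0, 0, 0)
  ncond <- stats$ncond %||% matrix(0, 0, 0)
  ssw <- stats$ssw %||% matrix(0, 0, 0)
  neff <- stats$neff %||% matrix(1, stats$I, J)
  ntrials <- stats$ntrials %||% rep(0, J)

  draws <- vector("list", config$n_chains)
  extras <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    if (!is.null(config$seed)) set.seed(config$seed + ch - 1L)
    init <- default_init(stats, J, likelihood, jitter = config$n_chains > 1L)
    if (rp$family == "lkj" && !likelihood) init$Sigma <- diag(rp$s^2, J)
    res <- run_mcmc_cpp(
      m = stats$m, neff = neff, abar = abar, ssw = ssw,
      ntrials = ntrials, ncond = ncond,
      design = design, prior_type = prior_type,
      v_or_eta = v_or_eta, S_iw = S_iw, s_vec = s_vec,
      fam = fam, fam_par = fam_par,
      mu_prior_var = mu_prior_var,
      fix_mu = !is.null(fix_mu),
      mu_fixed = if (is.null(fix_mu)) rep(0, J) else fix_mu,
      tau_a = 0.01, tau_b = tau_b, alpha_prior_var = alpha_prior_var,
      n_burn = config$n_burn, n_keep = config$n_keep,
      likelihood_on = likelihood, target_accept = config$target_accept,
      store_theta = store_theta, init = init)
    tb <- tibble::tibble(.chain = ch, .iteration = seq_len(config$n_keep))
    for (j in seq_len(J)) tb[[paste0("mu_", j)]] <- res$mu[, j]
    for (j in seq_len(J)) tb[[paste0("sigma_", j)]] <- res$sigma[, j]
    p <- 0L
    for (a in seq_len(J - 1L)) for (b in seq(a + 1L, J)) {
      p <- p + 1L
      tb[[rho_name(a, b)]] <- res$rho[, p]
    }
    if (design != 0L) for (j in seq_len(J)) tb[[paste0("tau_", j)]] <- res$tau[, j]
    draws[[ch]] <- tb
    extras[[ch]] <- res[c("theta_mean", "alpha_mean", "accept_rho",
                          "accept_sigma", "theta")]
  }
  list(draws = dplyr::bind_rows(draws), extras = extras)
}

build_fit <- function(run, stats, design, prior, rp, config, likelihood) {
  draws <- run$draws
  pars <- setdiff(names(draws), c(".chain", ".iteration"))
  diag_tb <- purrr::map_dfr(pars, function(p) {
    m <- matrix(draws[[p]], ncol = config$n_chains)
    tibble::tibble(parameter = p,
                   rhat = suppressWarnings(split_rhat(m)),
                   ess = suppressWarnings(bulk_ess(m)))
  })
  accept_rho <- run$extras[[1L]]$accept_rho
  if (rp$family == "lkj" && is.finite(accept_rho) && accept_rho < 0.05) {
    warning("LKJ correlation block acceptance below .05 after adaptation; ",
            "treat posterior summaries with caution")
  }
  theta_mean <- Reduce(`+`, lapply(run$extras, `[[`, "theta_mean")) /
    length(run$extras)
  structure(list(draws = draws, diagnostics = diag_tb,
                 accept = list(rho = accept_rho,
                               sigma = run$extras[[1L]]$accept_sigma),
                 theta_mean = theta_mean,
                 theta_draws = run$extras[[1L]]$theta,
                 design = c("manifest", "hierarchical", "contrast")[design + 1L],
                 prior = prior, config = config, likelihood = likelihood,
                 I = stats$I, J = stats$J),
            class = "corr_fit")
}

#' Fit the manifest multivariate-normal model
#'
#' `Y_i ~ N_J(mu, Sigma)` on observed scores, under any of the three priors
#' on `Sigma`. Appropriate when measurement error is negligible.
#'
#' @param data An `I x J` matrix (or data frame of scores only) of
#'   individual-by-variable scores, `I > J`.
#' @param prior A [prior_iw()], [prior_siw()], or [prior_lkj()].
#' @param config A [chain_config()].
#' @param likelihood Set `FALSE` to sample from the prior through the same
#'   machinery (no-data run).
#' @param fix_mu Optional known mean vector; when supplied, `mu` is held
#'   fixed (used mainly to exercise the conjugate closed form).
#' @return A `corr_fit`.
#' @export
fit_manifest <- function(data, prior, config = chain_config(),
                         likelihood = TRUE, fix_mu = NULL) {
  y <- as.matrix(data)
  if (!is.numeric(y)) stop("manifest data must be numeric")
  I <- nrow(y); J <- ncol(y)
  if (I <= J) stop("manifest model needs more individuals than variables")
  if (qr(scale(y, scale = FALSE))$rank < J) {
    stop("manifest data are rank-deficient; correlations are not identifiable")
  }
  stats <- list(I = I, J = J, m = unname(y), u = sd(y))
  fit_from_stats(stats, prior, config, design = 0L, likelihood = likelihood,
                 fix_mu = fix_mu)
}

#' Fit the hierarchical trial-level model
#'
#' `Y_ijl | theta_ij ~ N(theta_ij, tau_j^2)` with `theta_i ~ N_J(mu, Sigma)`.
#' The inverse Wishart and scaled inverse Wishart priors use fully conjugate
#' Gibbs updates; the LKJ prior uses adaptive Metropolis blocks on the
#' partial-correlation parameterization of `rho` and on `log sigma_j`.
#' Posterior correlations are recorded on every iteration from the `Sigma`
#' draw (IW/SIW) or the Cholesky cross product (LKJ).
#'
#' Diffuse conjugate priors complete the model: `mu_j ~ N(0, (100 u)^2)` and
#' `tau_j^2 ~ Inverse-Gamma(.01, .01 u^2)` with `u` the pooled SD of the
#' scores, so both are effectively flat on the data's scale.
#'
#' @param data Long-format trial tibble with columns `individual`, `task`,
#'   `score` (dense 1-based ids, every cell nonempty).
#' @inheritParams fit_manifest
#' @param store_theta Keep per-iteration true-score draws (memory-heavy).
#' @return A `corr_fit`: retained draws of `mu`, `sigma`, `rho`, `tau`
#'   (tibble, one row per iteration), split R-hat and bulk ESS per
#'   parameter, acceptance rates for the LKJ blocks, and posterior-mean true
#'   scores.
#' @export
fit_hierarchical <- function(data, prior, config = chain_config(),
                             likelihood = TRUE, store_theta = FALSE) {
  if ("condition" %in% names(data) && !all(is.na(data$condition))) {
    stop("data has conditions; use fit_contrast()")
  }
  stats <- prepare_hier_data(data)
  fit_from_stats(stats, prior, config, design = 1L, likelihood = likelihood,
                 store_theta = store_theta)
}

# shared fitting path once data are reduced to cell statistics
fit_from_stats <- function(stats, prior, config, design, likelihood = TRUE,
                           store_theta = FALSE, fix_mu = NULL) {
  rp <- resolve_prior(prior, stats$J)
  run <- run_chains(stats, rp, config, design = design, likelihood = likelihood,
                    store_theta = store_theta, fix_mu = fix_mu)
  build_fit(run, stats, design, prior, rp, config, likelihood)
}

#' Fit the two-condition contrast model
#'
#' `Y_ijkl ~ N(alpha_ij + x_k theta_ij, tau_j^2)` with contrast codes
#' `x = -.5, +.5`: `theta_ij` is the within-task condition effect (e.g., a
#' Stroop effect) and the multivariate layer `theta_i ~ N_J(mu, Sigma)`
#' applies to these slopes, so the correlation of interest is between
#' per-person effects. Intercepts get a diffuse conjugate normal prior.
#'
#' @param data Long-format trial tibble with columns `individual`, `task`,
#'   `condition` (1 = `x -.5`, 2 = `x +.5`), `score`; balanced within cells.
#' @inheritParams fit_hierarchical
#' @return A `corr_fit` (correlations refer to the slopes).
#' @export
fit_contrast <- function(data, prior, config = chain_config(),
                         likelihood = TRUE, store_theta = FALSE) {
  stats <- prepare_contrast_data(data)
  fit_from_stats(stats, prior, config, design = 2L, likelihood = likelihood,
                 store_theta = store_theta)
}

#' @export
print.corr_fit <- function(x, ...) {
  cat(sprintf("<corr_fit> %s model, %d x %d, %s prior; %d chain(s) x %d kept\n",
              x$design, x$I, x$J, x$prior$family,
              x$config$n_chains, x$config$n_keep))
  print(tidy(x), n = 12)
  invisible(x)
}

#' Tidy posterior summaries of a fitted model
#'
#' @param x A `corr_fit`.
#' @param conf.level Credible-interval mass (equal-tailed; default .95).
#' @param parameters Optional regexp to select parameters (e.g. `"^rho"`).
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (posterior mean), `std.error`
#'   (posterior SD), `conf.low`, `conf.high`, `rhat`, `ess`.
#' @export
tidy.corr_fit <- function(x, conf.level = 0.95, parameters = NULL, ...) {
  pars <- setdiff(names(x$draws), c(".chain", ".iteration"))
  if (!is.null(parameters)) pars <- grep(parameters, pars, value = TRUE)
  a <- (1 - conf.level) / 2
  out <- purrr::map_dfr(pars, function(p) {
    v <- x$draws[[p]]
    q <- unname(quantile(v, c(a, 1 - a)))
    tibble::tibble(term = p, estimate = mean(v), std.error = sd(v),
                   conf.low = q[1], conf.high = q[2])
  })
  left_join(out, x$diagnostics, by = c(term = "parameter"))
}

#' One-row model-level summary of a fitted model
#'
#' @param x A `corr_fit`.
#' @param ... Unused.
#' @return A tibble with chain counts, max split R-hat, min bulk ESS, and
#'   LKJ acceptance rates (NA for the Gibbs samplers).
#' @export
glance.corr_fit <- function(x, ...) {
  tibble::tibble(design = x$design, prior = x$prior$family,
                 n_chains = x$config$n_chains, n_kept = x$config$n_keep,
                 max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
                 min_ess = min(x$diagnostics$ess, na.rm = TRUE),
                 accept_rho = x$accept$rho %||% NA_real_,
                 accept_sigma = mean(x$accept$sigma))
}

#' @export
autoplot.corr_fit <- function(object, parameters = "^rho_", ...) {
  long <- tidyr::pivot_longer(object$draws,
                              cols = dplyr::matches(parameters),
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = .4) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "posterior draw", y = "density") +
    ggplot2::theme_minimal()
}

#' Serialize a fit's draws and diagnostics
#'
#' Writes retained draws as a long CSV (`chain, iteration, parameter, value`)
#' and diagnostics as JSON.
#'
#' @param fit A `corr_fit`.
#' @param draws_path,diagnostics_path Output file paths.
#' @return The paths, invisibly.
#' @export
write_fit <- function(fit, draws_path, diagnostics_path = NULL) {
  long <- tidyr::pivot_longer(fit$draws, cols = -c(".chain", ".iteration"),
                              names_to = "parameter", values_to = "value")
  names(long)[1:2] <- c("chain", "iteration")
  readr::write_csv(long, draws_path)
  if (!is.null(diagnostics_path)) {
    jsonlite::write_json(list(diagnostics = fit$diagnostics,
                              accept = fit$accept), diagnostics_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(c(draws_path, diagnostics_path))
}
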