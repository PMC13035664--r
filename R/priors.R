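# Prior families on the between-individual covariance matrix: inverse
# Wishart (IW), scaled inverse Wishart (SIW, the inverse-gamma mixture of
# inverse Wisharts), and LKJ on the correlation matrix with separate scale
# priors on standard deviations.

#' Prior specifications for the covariance matrix
#'
#' Constructors for the three supported prior families. Settings that depend
#' on the dimension `J` (the inverse-Wishart default `v = J + 1`, recycling
#' of scale vectors) are resolved when the prior meets data.
#'
#' * `prior_iw()`: `Sigma ~ Inverse Wishart(S, v)`. By default `v = J + 1`
#'   (marginally uniform correlations) and `S = diag(s^2)`, so `s` is the
#'   expected scale of the between-individual SDs.
#' * `prior_siw()`: the scaled inverse Wishart of shape `v` (default 2, which
#'   makes every pairwise correlation marginally uniform for all `J`) and
#'   scale vector `s` on standard deviations.
#' * `prior_lkj()`: `rho ~ LKJ(eta)` (default `eta = 1`, uniform over
#'   correlation matrices) with independent scale priors on each `sigma_j`,
#'   by default half-t with 2 degrees of freedom and scale `s`.
#'
#' @param s Scale setting: for `prior_iw()` the prior SD whose square fills
#'   the diagonal of `S`; for `prior_siw()`/`prior_lkj()` the scale (vector)
#'   on standard deviations.
#' @param v Degrees of freedom (IW: default `J + 1`; SIW: default 2).
#' @param S Full scale matrix for the IW prior (overrides `s`).
#' @param eta LKJ shape (default 1).
#' @param scale_family Scale-prior family for `prior_lkj()`: one of
#'   `"half_t_2"`, `"half_normal"`, `"half_cauchy"`, `"exponential"`,
#'   `"gamma"`, `"lognormal"`, `"uniform"`. Each is parameterized so that its
#'   center sits at the nominal scale `s` (mean `s` where the mean exists,
#'   scale `s` for the heavy-tailed half-t and half-Cauchy).
#' @return A `prior_spec` object.
#' @name prior_spec
NULL

#' @rdname prior_spec
#' @export
prior_iw <- function(s = 0.1, v = NULL, S = NULL) {
  if (!is.null(S)) {
    if (!is.matrix(S) || nrow(S) != ncol(S)) stop("S must be a square matrix")
  }
  structure(list(family = "iw", s = s, v = v, S = S),
            class = c("prior_iw", "prior_spec"))
}

#' @rdname prior_spec
#' @export
prior_siw <- function(v = 2, s = 0.1) {
  if (v <= 0) stop("SIW shape v must be positive")
  if (any(s <= 0)) stop("SIW scales must be positive")
  structure(list(family = "siw", v = v, s = s),
            class = c("prior_siw", "prior_spec"))
}

#' @rdname prior_spec
#' @export
prior_lkj <- function(eta = 1, s = 0.1, scale_family = "half_t_2") {
  if (eta <= 0) stop("LKJ shape eta must be positive")
  if (any(s <= 0)) stop("scales must be positive")
  scale_family <- match.arg(scale_family, names(scale_family_table))
  structure(list(family = "lkj", eta = eta, s = s, scale_family = scale_family),
            class = c("prior_lkj", "prior_spec"))
}

#' @export
print.prior_spec <- function(x, ...) {
  lab <- switch(x$family,
    iw = sprintf("Inverse Wishart(v = %s, S = %s)",
                 if (is.null(x$v)) "J + 1" else format(x$v),
                 if (is.null(x$S)) sprintf("diag(%g^2)", x$s[1]) else "user matrix"),
    siw = sprintf("Scaled inverse Wishart(v = %g, s = %s)", x$v,
                  paste(signif(x$s, 4), collapse = ", ")),
    lkj = sprintf("LKJ(eta = %g) with %s(s = %s) scales", x$eta, x$scale_family,
                  paste(signif(x$s, 4), collapse = ", ")))
  cat("<prior_spec>", lab, "\n")
  invisible(x)
}

# resolve dimension-dependent defaults against J; returns a plain list used
# by the samplers
resolve_prior <- function(prior, J) {
  stopifnot(inherits(prior, "prior_spec"))
  if (prior$family == "iw") {
    S <- prior$S %||% diag(rep_len(prior$s, J)^2, J)
    v <- prior$v %||% (J + 1)
    if (nrow(S) != J) stop("IW scale matrix has dimension ", nrow(S), ", expected ", J)
    if (v <= J - 1) stop("IW degrees of freedom must exceed J - 1")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("IW scale matrix must be positive definite")
    list(family = "iw", v = v, S = S)
  } else if (prior$family == "siw") {
    list(family = "siw", v = prior$v, s = rep_len(prior$s, J))
  } else {
    fam <- scale_family_params(prior$scale_family, rep_len(prior$s, J))
    list(family = "lkj", eta = prior$eta, s = rep_len(prior$s, J),
         scale_family = prior$scale_family, fam_id = fam$id, fam_par = fam$par)
  }
}

#' Split a covariance matrix into standard deviations and correlations
#'
#' Inverts `Sigma = D(sd) rho D(sd)`: `sd_j = sqrt(Sigma_jj)` and
#' `rho_jk = Sigma_jk / (sd_j sd_k)`.
#'
#' @param Sigma Symmetric covariance matrix with positive diagonal.
#' @return A list with `sd` (length-J vector) and `rho` (correlation matrix).
#' @export
corr_from_cov <- function(Sigma) {
  if (!is.matrix(Sigma) || nrow(Sigma) != ncol(Sigma)) stop("Sigma must be square")
  if (any(diag(Sigma) <= 0)) stop("Sigma must have a positive diagonal")
  sd <- sqrt(diag(Sigma))
  rho <- Sigma / tcrossprod(sd)
  diag(rho) <- 1
  list(sd = sd, rho = rho)
}

#' Draw covariance matrices from the inverse Wishart prior
#'
#' Samples `Sigma ~ Inverse Wishart(S, v)` by drawing from the Wishart with
#' the inverted scale and inverting each draw.
#'
#' @param spec A [prior_iw()] (or `NULL` to use `v`, `S` directly).
#' @param J Dimension.
#' @param n_draws Number of draws.
#' @param seed Optional integer seed.
#' @param v,S Direct settings, used when `spec` is `NULL`.
#' @return A `J x J x n_draws` array.
#' @export
sample_iw <- function(spec = NULL, J, n_draws, seed = NULL, v = NULL, S = NULL) {
  if (!is.null(spec)) {
    rp <- resolve_prior(spec, J)
    v <- rp$v; S <- rp$S
  } else {
    S <- S %||% diag(J)
    v <- v %||% (J + 1)
  }
  if (v <= J - 1) stop("inverse Wishart requires v > J - 1")
  Sinv <- tryCatch(solve(S), error = function(e) stop("IW scale matrix is singular"))
  if (!is.null(seed)) set.seed(seed)
  W <- rWishart(n_draws, df = v, Sigma = Sinv)
  out <- array(apply(W, 3L, solve), dim = c(J, J, n_draws))
  out
}

#' Draw covariance matrices from the scaled inverse Wishart prior
#'
#' Uses the exact two-stage mixture representation:
#' `alpha_j ~ Inverse-Gamma(1/2, 1/s_j^2)` independently, then
#' `Sigma | alpha ~ Inverse Wishart(v + J - 1, 2v D(1/alpha))`.
#'
#' @param spec A [prior_siw()].
#' @param J Dimension.
#' @param n_draws Number of draws.
#' @param seed Optional integer seed.
#' @return A `J x J x n_draws` array.
#' @export
sample_siw <- function(spec, J, n_draws, seed = NULL) {
  rp <- resolve_prior(spec, J)
  if (!is.null(seed)) set.seed(seed)
  v <- rp$v; s <- rp$s
  alpha <- matrix(1 / rgamma(n_draws * J, shape = 0.5, rate = rep(1 / s^2, each = n_draws)),
                  n_draws, J)
  df <- v + J - 1
  out <- array(0, dim = c(J, J, n_draws))
  for (d in seq_len(n_draws)) {
    # scale Psi = 2v * diag(1/alpha); Wishart needs Psi^{-1} = diag(alpha)/(2v)
    W <- rWishart(1L, df = df, Sigma = diag(alpha[d, ] / (2 * v), J))[, , 1L]
    out[, , d] <- solve(W)
  }
  out
}

#' Draw correlation matrices from the LKJ prior
#'
#' Uses the onion (canonical partial correlation) construction: independent
#' shifted-Beta partial correlations are mapped to a Cholesky factor whose
#' cross product is the correlation matrix.
#'
#' @param eta LKJ shape (> 0).
#' @param J Dimension (>= 2).
#' @param n_draws Number of draws.
#' @param seed Optional integer seed.
#' @return A `J x J x n_draws` array of correlation matrices.
#' @export
sample_lkj_corr <- function(eta, J, n_draws, seed = NULL) {
  if (eta <= 0) stop("eta must be positive")
  if (J < 2) stop("J must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  lkj_onion_cpp(as.integer(n_draws), as.integer(J), eta)
}

# supported scale-prior families; par entries are resolved against s
scale_family_table <- list(
  half_t_2    = list(id = 1L),
  half_normal = list(id = 2L),
  half_cauchy = list(id = 3L),
  exponential = list(id = 4L),
  gamma       = list(id = 5L),
  lognormal   = list(id = 6L),
  uniform     = list(id = 7L)
)

# map (family, s) to the C++ density id and two parameter vectors (one row
# per task). Centering convention: mean = s where the mean exists; scale = s
# for half-t(2) and half-Cauchy.
scale_family_params <- function(family, s) {
  id <- scale_family_table[[family]]$id
  par <- switch(family,
    half_t_2    = cbind(2, s),                        # df, scale
    half_normal = cbind(s * sqrt(pi / 2), 0),         # sd (mean = s)
    half_cauchy = cbind(s, 0),                        # scale
    exponential = cbind(s, 0),                        # scale (mean = s)
    gamma       = cbind(2, s / 2),                    # shape, scale (mean = s)
    lognormal   = cbind(log(s) - 0.125, 0.5),         # meanlog, sdlog (mean = s)
    uniform     = cbind(2 * s, 0))                    # upper (mean = s)
  list(id = id, par = par)
}

#' Draw from a scale-prior family on standard deviations
#'
#' @param family One of `"half_t_2"`, `"half_normal"`, `"half_cauchy"`,
#'   `"exponential"`, `"gamma"`, `"lognormal"`, `"uniform"`.
#' @param s Nominal scale; each family is parameterized so its center sits at
#'   `s` (see [prior_lkj()]).
#' @param n_draws Number of draws.
#' @param seed Optional integer seed.
#' @return A vector of positive draws.
#' @export
sample_scale <- function(family, s, n_draws, seed = NULL) {
  if (!family %in% names(scale_family_table)) {
    stop("unknown scale family '", family, "'; supported: ",
         paste(names(scale_family_table), collapse = ", "))
  }
  if (s <= 0) stop("s must be positive")
  if (!is.null(seed)) set.seed(seed)
  switch(family,
    half_t_2    = s * abs(rt(n_draws, df = 2)),
    half_normal = abs(rnorm(n_draws, 0, s * sqrt(pi / 2))),
    half_cauchy = abs(rcauchy(n_draws, 0, s)),
    exponential = rexp(n_draws, rate = 1 / s),
    gamma       = rgamma(n_draws, shape = 2, rate = 2 / s),
    lognormal   = rlnorm(n_draws, meanlog = log(s) - 0.125, sdlog = 0.5),
    uniform     = runif(n_draws, 0, 2 * s))
}

#' Tidy draws of standard deviations and correlations from covariance draws
#'
#' @param Sigma_draws A `J x J x n` array of covariance (or correlation)
#'   matrices.
#' @return A tibble with one row per draw: columns `.draw`, `sigma_1 ...
#'   sigma_J`, and `rho_j_k` for every pair `j < k`.
#' @export
prior_draws_tibble <- function(Sigma_draws) {
  J <- dim(Sigma_draws)[1L]
  n <- dim(Sigma_draws)[3L]
  sds <- sqrt(t(apply(Sigma_draws, 3L, diag)))
  if (J == 1L) sds <- matrix(sqrt(Sigma_draws[1, 1, ]), ncol = 1L)
  out <- tibble::tibble(.draw = seq_len(n))
  for (j in seq_len(J)) out[[paste0("sigma_", j)]] <- sds[, j]
  for (j in seq_len(J - 1L)) {
    for (k in seq((j + 1L), J)) {
      out[[rho_name(j, k)]] <- Sigma_draws[j, k, ] / (sds[, j] * sds[, k])
    }
  }
  out
}

rho_name <- function(j, k) paste0("rho_", j, "_", k)
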