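# Synthetic-data generation: true scores, trial-level data, manifest scores.
# All functions are deterministic given `seed`; when `seed` is NULL the
# current RNG stream is used (this is what simulate_experiment() relies on to
# draw true scores and trial noise from one stream).

#' Sample true scores from the individual-level model
#'
#' Draws `I` rows i.i.d. from `N_J(mu, D(sigma) rho D(sigma))`: each row is
#' one individual's vector of latent (error-free) task scores.
#'
#' @param gt A [make_ground_truth()] object.
#' @param seed Optional integer seed.
#' @return An `I x J` numeric matrix of true scores `theta`.
#' @export
sample_true_scores <- function(gt, seed = NULL) {
  validate_ground_truth(gt)
  if (!is.null(seed)) set.seed(seed)
  Sigma <- true_cov(gt)
  theta <- rmvnorm_rows(gt$I, gt$mu, Sigma)
  dimnames(theta) <- list(NULL, paste0("task_", seq_len(gt$J)))
  theta
}

# rows iid N(mu, Sigma); tolerates positive-semidefinite Sigma (zero variances)
rmvnorm_rows <- function(n, mu, Sigma) {
  J <- length(mu)
  Z <- matrix(rnorm(n * J), n, J)
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    e <- eigen(Sigma, symmetric = TRUE)
    R <- diag(sqrt(pmax(e$values, 0)), J) %*% t(e$vectors)
  }
  sweep(Z %*% R, 2L, mu, "+")
}

#' Sample trial-level observations around true scores
#'
#' For hierarchical designs, emits `L` replicates per (individual, task) cell
#' with noise SD `tau_j`. For contrast designs, each (individual, task) cell
#' has two conditions with means `alpha_ij + x_k * theta_ij`
#' (`x = -.5, +.5`), `L` replicates per condition; the per-individual
#' intercepts `alpha_ij` are drawn i.i.d. from the ground truth's intercept
#' distribution and attached as the `"alpha"` attribute.
#'
#' @param gt A [make_ground_truth()] object (hierarchical or contrast design).
#' @param theta `I x J` matrix of true scores (slopes, for contrast designs).
#' @param seed Optional integer seed.
#' @return A tibble with columns `individual`, `task`, (`condition`,)
#'   `replicate`, `score`, carrying `gt` as the `"ground_truth"` attribute.
#' @export
sample_trials <- function(gt, theta, seed = NULL) {
  validate_ground_truth(gt)
  if (!identical(dim(theta), c(gt$I, gt$J))) {
    stop("theta must be an I x J matrix conformable with gt")
  }
  if (!is.null(seed)) set.seed(seed)
  I <- gt$I; J <- gt$J; L <- gt$L

  if (identical(gt$design, "contrast")) {
    alpha <- matrix(rnorm(I * J, gt$intercept_mean, gt$intercept_sd), I, J)
    codes <- sort(gt$contrast_codes)
    individual <- rep(seq_len(I), each = J * 2L * L)
    task <- rep(rep(seq_len(J), each = 2L * L), times = I)
    condition <- rep(rep(1:2, each = L), times = I * J)
    replicate <- rep(seq_len(L), times = I * J * 2L)
    cell_mean <- alpha[cbind(individual, task)] +
      codes[condition] * theta[cbind(individual, task)]
    score <- rnorm(length(cell_mean), cell_mean, gt$tau[task])
    out <- tibble::tibble(individual, task, condition, replicate, score)
    attr(out, "alpha") <- alpha
  } else {
    individual <- rep(seq_len(I), each = J * L)
    task <- rep(rep(seq_len(J), each = L), times = I)
    replicate <- rep(seq_len(L), times = I * J)
    score <- rnorm(I * J * L, theta[cbind(individual, task)], gt$tau[task])
    out <- tibble::tibble(individual, task, replicate, score)
  }
  attr(out, "ground_truth") <- gt
  out
}

#' Sample a manifest dataset
#'
#' Draws `I` individuals directly from `N_J(mu, D(sigma) rho D(sigma))` with
#' no replicate structure: the conventional case where scores are treated as
#' measured without error.
#'
#' @param gt A manifest-design [make_ground_truth()] or
#'   [make_manifest_truth()] object.
#' @param seed Optional integer seed.
#' @return An `I x J` matrix of observed scores.
#' @export
sample_manifest <- function(gt, seed = NULL) {
  validate_ground_truth(gt)
  if (!identical(gt$design, "manifest")) {
    stop("sample_manifest() requires a manifest-design ground truth")
  }
  y <- sample_true_scores(gt, seed = seed)
  attr(y, "ground_truth") <- gt
  y
}

#' Generate one complete synthetic experiment
#'
#' Seeds the RNG once and then draws true scores followed by trial noise (or
#' the manifest scores) from that single stream, so a replicate is fully
#' reproducible from one integer.
#'
#' @param gt A [make_ground_truth()] object.
#' @param seed Integer seed for the replicate.
#' @return A list with `theta` (I x J true scores) and `data` (trial tibble,
#'   or the manifest score matrix for manifest designs).
#' @export
simulate_experiment <- function(gt, seed) {
  validate_ground_truth(gt)
  set.seed(seed)
  if (identical(gt$design, "manifest")) {
    y <- sample_manifest(gt, seed = NULL)
    list(theta = y, data = y)
  } else {
    theta <- sample_true_scores(gt, seed = NULL)
    list(theta = theta, data = sample_trials(gt, theta, seed = NULL))
  }
}

#' Write / read trial data as long-format CSV
#'
#' The file has header `individual,task,condition,replicate,score`; the
#' condition column is left blank for non-contrast designs.
#'
#' @param data A trial tibble from [sample_trials()] (or of the same shape).
#' @param path File path.
#' @return `read_trials()` returns the trial tibble; `write_trials()` returns
#'   `path` invisibly.
#' @export
write_trials <- function(data, path) {
  out <- as_tibble(data)
  if (!"condition" %in% names(out)) out$condition <- NA_integer_
  out <- out[, c("individual", "task", "condition", "replicate", "score")]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    individual = readr::col_integer(), task = readr::col_integer(),
    condition = readr::col_integer(), replicate = readr::col_integer(),
    score = readr::col_double()))
  if (all(is.na(out$condition))) out$condition <- NULL
  out
}
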