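# Convergence diagnostics: rank-normalized split R-hat and bulk effective
# sample size (Vehtari, Gelman, Simpson, Carpenter & Burkner, 2021).

# draws as iterations x chains matrix; vectors are treated as one chain
as_draws_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  x
}

split_chains <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  x <- x[seq_len(2L * half), , drop = FALSE]
  cbind(x[seq_len(half), , drop = FALSE],
        x[half + seq_len(half), , drop = FALSE])
}

# rank-normalize jointly across all chains (fractional offset 3/8)
rank_normalize <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

rhat_basic <- function(z) {
  n <- nrow(z); m <- ncol(z)
  W <- mean(apply(z, 2L, var))
  B <- n * var(colMeans(z))
  if (W == 0) return(NaN)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split R-hat
#'
#' Chains are split in half, the pooled draws are rank-normalized, and the
#' classic between/within potential scale reduction factor is computed on
#' the normal scores; the reported value is the maximum of this bulk
#' statistic and the same statistic on folded (median-absolute-deviation)
#' scores, which is sensitive to scale disagreement.
#'
#' @param x A numeric vector (one chain) or an iterations x chains matrix.
#' @return The split R-hat (>= 1 up to Monte Carlo noise); `NaN` with a
#'   warning for constant chains.
#' @export
split_rhat <- function(x) {
  x <- as_draws_matrix(x)
  if (nrow(x) < 20L) stop("split_rhat() needs at least 10 iterations per half-chain")
  if (all(x == x[1L])) {
    warning("constant chains: split R-hat is undefined")
    return(NaN)
  }
  z <- split_chains(x)
  bulk <- rhat_basic(rank_normalize(z))
  folded <- rhat_basic(rank_normalize(abs(z - median(z))))
  max(bulk, folded, na.rm = TRUE)
}

# chain autocovariance via FFT (biased, as in the reference algorithm)
autocov_fft <- function(v) {
  n <- length(v)
  v <- v - mean(v)
  M <- nextn(2L * n)
  f <- fft(c(v, rep(0, M - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / M
  ac / n
}

#' Bulk effective sample size
#'
#' Rank-normalizes the split chains and sums autocorrelations with Geyer's
#' initial monotone sequence truncation, combining chains by the
#' multi-chain variance decomposition. Negatively autocorrelated chains may
#' legitimately return an ESS larger than the number of draws.
#'
#' @param x A numeric vector (one chain) or an iterations x chains matrix.
#' @return The bulk ESS (> 0); `NaN` with a warning for constant chains.
#' @export
bulk_ess <- function(x) {
  x <- as_draws_matrix(x)
  if (nrow(x) < 50L) stop("bulk_ess() needs at least 50 iterations")
  if (all(x == x[1L])) {
    warning("constant chains: bulk ESS is undefined")
    return(NaN)
  }
  z <- rank_normalize(split_chains(x))
  n <- nrow(z); m <- ncol(z)
  acov <- apply(z, 2L, autocov_fft)            # n x m, biased autocovariances
  chain_var <- acov[1L, ] * n / (n - 1)
  W <- mean(chain_var)
  var_plus <- W * (n - 1) / n
  if (m > 1L) var_plus <- var_plus + var(colMeans(z))
  if (var_plus == 0) return(NaN)

  rho <- 1 - (W - rowMeans(acov)) / var_plus    # rho[1] corresponds to lag 0
  # Geyer paired sums over (even, odd) lags: P_k = rho_{2k} + rho_{2k+1}
  max_pair <- floor(n / 2) - 1L
  tau <- -1
  prev <- Inf
  for (k in 0:max_pair) {
    i <- 2L * k + 1L                            # lag 2k at index 2k+1
    if (i + 1L > n) break
    p <- rho[i] + rho[i + 1L]
    if (p < 0) break                            # initial positive sequence
    p <- min(p, prev)                           # enforce monotone decrease
    tau <- tau + 2 * p
    prev <- p
  }
  tau <- max(tau, 1 / log10(n * m + 1))         # guard against tau <= 0
  n * m / tau
}
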