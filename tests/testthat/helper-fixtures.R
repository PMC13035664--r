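# Shared fixtures: small ground truths and short chain configs used across
# the unit tests. Everything is generated in code under fixed seeds.

quick_config <- function(seed = 1L, n_burn = 200L, n_keep = 400L, n_chains = 1L) {
  chain_config(n_burn = n_burn, n_keep = n_keep, n_chains = n_chains, seed = seed)
}

small_two_task <- function(rho = .5, tau = .2, I = 60L, L = 8L) {
  make_ground_truth("two_task", rho = rho, tau = tau, I = I, L = L)
}

small_trials <- function(gt = small_two_task(), seed = 11L) {
  simulate_experiment(gt, seed)$data
}

# two-sided KS p-value against a CDF, with jitter to break MCMC ties
ks_pvalue <- function(x, cdf, ...) {
  x <- x + runif(length(x), -1e-12, 1e-12)
  suppressWarnings(stats::ks.test(x, cdf, ...)$p.value)
}

half_t_cdf <- function(scale, df = 2) {
  function(q) 2 * stats::pt(q / scale, df) - 1
}
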