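test_that("manifest IW sampler with known mean matches the conjugate closed form", {
  gt <- make_manifest_truth(J = 2, rho_pair = .5, I = 100L, sigma = c(2, 1))
  y <- sample_manifest(gt, seed = 201)
  fit <- fit_manifest(y, prior_iw(S = diag(2), v = 3), quick_config(seed = 202, n_keep = 3000),
                      fix_mu = gt$mu)
  SS <- crossprod(sweep(y, 2, gt$mu))
  direct <- sample_iw(NULL, J = 2, n_draws = 12000, seed = 203, v = 3 + 100, S = diag(2) + SS)
  rho_direct <- direct[1, 2, ] / sqrt(direct[1, 1, ] * direct[2, 2, ])
  for (q in c(.1, .5, .9)) {
    mce <- 3 * sd(rho_direct) / sqrt(1000)
    expect_lt(abs(quantile(fit$draws$rho_1_2, q) - quantile(rho_direct, q)), 5 * mce + .01)
  }
})

test_that("samplers with the likelihood disabled reproduce their prior marginals", {
  d <- small_trials(small_two_task(I = 10L, L = 4L))
  cfg <- chain_config(n_burn = 500, n_keep = 3000, seed = 204)

  f_iw <- fit_hierarchical(d, prior_iw(s = .1), cfg, likelihood = FALSE)
  expect_gt(ks_pvalue(f_iw$draws$rho_1_2, "punif", -1, 1), .01)

  # the SIW Gibbs chain mixes sigma slowly (alpha | Sigma alternation), so
  # thin heavily before the exactness test
  f_siw <- fit_hierarchical(d, prior_siw(s = .1),
                            chain_config(n_burn = 500, n_keep = 9000, seed = 204),
                            likelihood = FALSE)
  thin <- seq(1, 9000, by = 15)
  expect_gt(ks_pvalue(f_siw$draws$rho_1_2[thin], "punif", -1, 1), .01)
  expect_gt(ks_pvalue(f_siw$draws$sigma_1[thin], half_t_cdf(.1)), .005)

  f_lkj <- fit_hierarchical(d, prior_lkj(s = .1),
                            chain_config(n_burn = 2000, n_keep = 6000, seed = 205),
                            likelihood = FALSE)
  thin <- seq(1, 6000, by = 12)
  expect_gt(ks_pvalue(f_lkj$draws$rho_1_2[thin], "punif", -1, 1), .01)
  expect_gt(ks_pvalue(f_lkj$draws$sigma_1[thin], half_t_cdf(.1)), .005)
})

test_that("SIW mixing-variable full conditional matches quadrature", {
  # fix Sigma; the conditional density of alpha_j follows from the mixture
  # representation alone: IW(v+J-1, 2v D(1/alpha)) x IG(1/2, 1/s^2)
  v <- 2; s <- .1; J <- 2
  Sigma <- matrix(c(.02, .008, .008, .015), 2, 2)
  Siginv <- solve(Sigma)
  nu <- v + J - 1
  dens <- function(a) a^(-nu / 2) * exp(-v * Siginv[1, 1] / a) *
    a^(-1 / 2 - 1) * exp(-(1 / s^2) / a)
  grid <- seq(1e-4, 50, length.out = 2e5)
  w <- dens(grid); cdf_grid <- cumsum(w) / sum(w)
  quad_cdf <- approxfun(grid, cdf_grid, yleft = 0, yright = 1)
  # the update rule used by the Gibbs sampler
  set.seed(206)
  draws <- 1 / rgamma(2e4, shape = (v + J) / 2, rate = v * Siginv[1, 1] + 1 / s^2)
  draws <- draws[draws < 50]
  expect_gt(ks_pvalue(draws, quad_cdf), .01)
})

test_that("LKJ and IW posteriors agree on the same two-task data", {
  gt <- small_two_task(rho = .5, tau = .2, I = 150L, L = 20L)
  d <- small_trials(gt, seed = 207)
  cfg <- chain_config(seed = 208)
  f_iw <- fit_hierarchical(d, prior_iw(s = .1), cfg)
  f_lkj <- fit_hierarchical(d, prior_lkj(s = .1), cfg)
  m_iw <- mean(f_iw$draws$rho_1_2); m_lkj <- mean(f_lkj$draws$rho_1_2)
  ess <- min(f_iw$diagnostics$ess[f_iw$diagnostics$parameter == "rho_1_2"],
             f_lkj$diagnostics$ess[f_lkj$diagnostics$parameter == "rho_1_2"])
  mcse <- sd(f_lkj$draws$rho_1_2) / sqrt(ess)
  expect_lt(abs(m_iw - m_lkj), 4 * mcse + .01)
})

test_that("the hierarchical model collapses to the manifest model as tau -> 0", {
  gt <- small_two_task(rho = .6, tau = 1e-6, I = 120L, L = 5L)
  d <- small_trials(gt, seed = 209)
  cells <- averaged_scores(d)
  f_h <- fit_hierarchical(d, prior_iw(s = .1), chain_config(seed = 210))
  f_m <- fit_manifest(cells, prior_iw(s = .1), chain_config(seed = 210))
  expect_lt(abs(mean(f_h$draws$rho_1_2) - mean(f_m$draws$rho_1_2)), .01)
})

test_that("contrast fits recover slopes and their correlation", {
  gt <- make_ground_truth("contrast", tau = 0, I = 150L, L = 4L)
  sim <- simulate_experiment(gt, 211)
  f <- fit_contrast(sim$data, prior_iw(s = 25), quick_config(seed = 212))
  r_true <- cor(sim$theta)[1, 2]
  expect_lt(abs(mean(f$draws$rho_1_2) - r_true), .02)
  expect_lt(max(abs(f$theta_mean - sim$theta)), .02 * max(abs(sim$theta)))

  bad <- dplyr::filter(sim$data, .data$condition == 1L)
  expect_error(fit_contrast(bad, prior_iw(s = 25)), "2 conditions")
  unb <- sim$data[-1L, ]
  expect_error(fit_contrast(unb, prior_iw(s = 25)), "nonempty|unbalanced")
})

test_that("fits are reproducible and intervals are ordered", {
  d <- small_trials(seed = 213)
  for (p in list(prior_iw(s = .1), prior_siw(s = .1), prior_lkj(s = .1))) {
    f1 <- fit_hierarchical(d, p, quick_config(seed = 214))
    f2 <- fit_hierarchical(d, p, quick_config(seed = 214))
    expect_identical(f1$draws, f2$draws)
    td <- tidy(f1)
    expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  }
})

test_that("multi-chain fits report diagnostics and tidy/glance behave", {
  d <- small_trials(seed = 215)
  f <- fit_hierarchical(d, prior_iw(s = .1), quick_config(seed = 216, n_chains = 4L))
  g <- glance(f)
  expect_equal(g$n_chains, 4L)
  expect_lt(g$max_rhat, 1.05)
  expect_gt(g$min_ess, 100)
  td <- tidy(f, parameters = "^rho")
  expect_equal(td$term, "rho_1_2")
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("fit serialization writes long draws and diagnostics", {
  d <- small_trials(seed = 217)
  f <- fit_hierarchical(d, prior_iw(s = .1), quick_config(seed = 218))
  dir <- withr::local_tempdir()
  paths <- write_fit(f, file.path(dir, "draws.csv"), file.path(dir, "diag.json"))
  long <- readr::read_csv(file.path(dir, "draws.csv"), show_col_types = FALSE)
  expect_setequal(names(long), c("chain", "iteration", "parameter", "value"))
  expect_equal(nrow(long), 400 * (2 + 2 + 1 + 2))
  expect_true(jsonlite::validate(paste(readLines(file.path(dir, "diag.json")), collapse = ""))[1])
})

test_that("malformed data are rejected", {
  d <- small_trials(seed = 219)
  expect_error(fit_hierarchical(d[!(d$individual == 3L & d$task == 1L), ],
                                prior_iw(s = .1)),
               "nonempty")
  d2 <- d; d2$individual[d2$individual == 1L] <- 99L
  expect_error(fit_hierarchical(d2, prior_iw(s = .1)), "dense")
  y <- cbind(1:10, 2 * (1:10))
  expect_error(fit_manifest(y, prior_iw()), "rank-deficient")
  expect_error(fit_manifest(matrix(rnorm(6), 2, 3), prior_iw()), "more individuals")
})
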