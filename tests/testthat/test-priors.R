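test_that("corr_from_cov inverts the covariance decomposition", {
  out <- corr_from_cov(matrix(c(4, 2, 2, 4), 2, 2))
  expect_equal(out$sd, c(2, 2))
  expect_equal(out$rho[1, 2], .5)

  expect_equal(corr_from_cov(diag(c(1, 4, 9)))$rho, diag(3))

  set.seed(21)
  A <- matrix(rnorm(25), 5)
  Sigma <- crossprod(A) + diag(5)
  out <- corr_from_cov(Sigma)
  expect_equal(diag(out$sd) %*% out$rho %*% diag(out$sd), Sigma, tolerance = 1e-12)

  expect_error(corr_from_cov(matrix(c(0, 0, 0, 1), 2, 2)), "positive diagonal")
})

test_that("inverse Wishart correlations are marginally uniform at v = J + 1", {
  for (J in c(2, 3, 5, 8)) {
    d <- sample_iw(NULL, J = J, n_draws = 1e5, seed = 100 + J, v = J + 1)
    rho12 <- d[1, 2, ] / sqrt(d[1, 1, ] * d[2, 2, ])
    expect_gt(ks_pvalue(rho12, "punif", -1, 1), .01)
  }
})

test_that("inverse Wishart moments and 1-D reduction match closed forms", {
  S <- matrix(c(2, .5, .5, 1), 2, 2)
  d <- sample_iw(NULL, J = 2, n_draws = 4e4, seed = 31, v = 5, S = S)
  expect_equal(apply(d, c(1, 2), mean), S / (5 - 2 - 1), tolerance = .05)

  # J = 1: IW(s, v) is Inverse-Gamma(v/2, s/2)
  d1 <- sample_iw(NULL, J = 1, n_draws = 4e4, seed = 32, v = 5, S = matrix(2))
  expect_gt(ks_pvalue(1 / d1[1, 1, ], "pgamma", shape = 5 / 2, rate = 2 / 2), .01)

  expect_error(sample_iw(NULL, J = 2, n_draws = 10, v = .5), "v > J - 1")
  expect_error(sample_iw(NULL, J = 2, n_draws = 10, S = matrix(0, 2, 2)), "singular")
})

test_that("scaled inverse Wishart marginals are uniform and half-t", {
  for (J in c(2, 5)) {
    d <- sample_siw(prior_siw(v = 2, s = .1), J = J, n_draws = 5e4, seed = 40 + J)
    rho12 <- d[1, 2, ] / sqrt(d[1, 1, ] * d[2, 2, ])
    expect_gt(ks_pvalue(rho12, "punif", -1, 1), .01)
    expect_gt(ks_pvalue(sqrt(d[1, 1, ]), half_t_cdf(.1)), .01)
  }
})

test_that("two independent routes through the SIW mixture agree", {
  # reference: naive draw-by-draw re-derivation of the two-stage mixture
  naive_siw <- function(n, J, v, s, seed) {
    set.seed(seed)
    out <- array(0, c(J, J, n))
    for (d in seq_len(n)) {
      alpha <- 1 / rgamma(J, shape = 1 / 2, rate = 1 / s^2)
      Psi <- 2 * v * diag(1 / alpha, J)
      W <- rWishart(1, df = v + J - 1, Sigma = solve(Psi))[, , 1]
      out[, , d] <- solve(W)
    }
    out
  }
  a <- sample_siw(prior_siw(v = 2, s = .2), J = 2, n_draws = 4e4, seed = 50)
  b <- naive_siw(4e4, J = 2, v = 2, s = .2, seed = 51)
  # compare the (sd1, rho12) marginals by two-sample KS
  expect_gt(suppressWarnings(ks.test(sqrt(a[1, 1, ]), sqrt(b[1, 1, ]))$p.value), .01)
  ra <- a[1, 2, ] / sqrt(a[1, 1, ] * a[2, 2, ])
  rb <- b[1, 2, ] / sqrt(b[1, 1, ] * b[2, 2, ])
  expect_gt(suppressWarnings(ks.test(ra, rb)$p.value), .01)
})

test_that("LKJ marginals follow the shifted Beta closed form", {
  for (J in c(2, 4, 8)) {
    for (eta in c(.25, .5, 1, 2, 4)) {
      d <- sample_lkj_corr(eta, J, n_draws = 1e5, seed = round(1000 * eta) + J)
      a <- eta + (J - 2) / 2
      expect_gt(ks_pvalue((d[1, 2, ] + 1) / 2, "pbeta", a, a), .01)
    }
  }
})

test_that("LKJ draws are valid correlation matrices that thin near +/-1 as J grows", {
  d <- sample_lkj_corr(1, 5, n_draws = 2000, seed = 61)
  expect_true(all(abs(d[1, 1, ] - 1) < 1e-12))
  sym_err <- max(abs(d - aperm(d, c(2, 1, 3))))
  expect_lt(sym_err, 1e-12)
  min_eig <- min(apply(d, 3, function(m) min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)))
  expect_gt(min_eig, -1e-10)

  d2 <- sample_lkj_corr(1, 2, n_draws = 2e4, seed = 62)
  d8 <- sample_lkj_corr(1, 8, n_draws = 2e4, seed = 63)
  expect_gt(mean(abs(d2[1, 2, ]) > .8), 2 * mean(abs(d8[1, 2, ]) > .8))
})

test_that("LKJ onion construction matches brute-force rejection at J = 3", {
  # rejection oracle: uniform cube, keep positive-definite matrices (eta = 1)
  set.seed(64)
  r <- matrix(runif(3e5 * 3, -1, 1), ncol = 3)
  pd <- 1 + 2 * r[, 1] * r[, 2] * r[, 3] - r[, 1]^2 - r[, 2]^2 - r[, 3]^2 > 0
  oracle <- r[pd, 1]
  d <- sample_lkj_corr(1, 3, n_draws = 2e4, seed = 65)
  expect_gt(suppressWarnings(ks.test(d[1, 2, ], oracle)$p.value), .01)
})

test_that("scale families are positive and centered at their nominal scale", {
  for (fam in c("half_t_2", "half_normal", "half_cauchy", "exponential",
                "gamma", "lognormal", "uniform")) {
    x <- sample_scale(fam, s = .1, n_draws = 2e4, seed = 70)
    expect_true(all(x > 0))
    expect_lt(abs(median(x) / .1 - 1), 1)  # center within a factor of 2 of s
  }
  x <- sample_scale("half_t_2", s = .1, n_draws = 1e5, seed = 71)
  expect_equal(median(x), .1 * qt(.75, df = 2), tolerance = .02)
  xe <- sample_scale("exponential", s = .1, n_draws = 1e5, seed = 72)
  expect_equal(mean(xe), .1, tolerance = .02)
  expect_error(sample_scale("triangular", .1, 10), "supported")
})
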