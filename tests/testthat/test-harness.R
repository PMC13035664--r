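# A single small study is shared by several blocks below.
gt_small <- make_ground_truth("two_task", rho = .5, tau = .2, I = 80L, L = 10L)
study_small <- run_study(gt_small, n_replicates = 12L,
                         config = chain_config(n_burn = 300L, n_keep = 600L),
                         base_seed = 300L)

test_that("studies rerun byte-identically from the same base seed", {
  again <- run_study(gt_small, n_replicates = 12L,
                     config = chain_config(n_burn = 300L, n_keep = 600L),
                     base_seed = 300L)
  expect_identical(study_small$replicates, again$replicates)
})

test_that("rmse_table matches a brute-force recomputation", {
  tb <- rmse_table(study_small, reference = "population")
  reps <- study_small$replicates
  for (i in seq_len(nrow(tb))) {
    e <- reps$estimate[reps$method == tb$method[i]]
    expect_equal(tb$rmse[i], sqrt(mean((e - .5)^2)), tolerance = 1e-12)
  }
  tbr <- rmse_table(study_small, reference = "realized")
  ref <- reps$estimate[reps$method == "true_scores"]
  for (i in seq_len(nrow(tbr))) {
    e <- reps$estimate[reps$method == tbr$method[i]]
    expect_equal(tbr$rmse[i], sqrt(mean((e - ref)^2)), tolerance = 1e-12)
  }
  expect_false("true_scores" %in% tbr$method)

  # constant bias with zero variance gives RMSE |b|
  fake <- study_small
  fake$replicates <- dplyr::mutate(fake$replicates, estimate = .data$truth + .07)
  expect_true(all(abs(rmse_table(fake, "population")$rmse - .07) < 1e-12))
})

test_that("coverage bookkeeping is consistent with the intervals", {
  ct <- coverage_table(study_small)
  reps <- dplyr::filter(study_small$replicates, !is.na(.data$covered))
  expect_true(all(reps$covered ==
    (reps$truth >= reps$conf.low & reps$truth <= reps$conf.high)))
  expect_true(all(ct$coverage >= 0 & ct$coverage <= 1))
  expect_equal(sum(ct$n_missed), sum(!reps$covered))

  # intervals spanning [-1, 1] always cover
  fake <- study_small
  fake$replicates$conf.low <- -1; fake$replicates$conf.high <- 1
  fake$replicates$covered <- TRUE
  expect_true(all(coverage_table(fake)$coverage == 1))

  expect_equal(
    pooled_coverage(study_small, methods = "IW", first_n = 6L),
    mean(dplyr::filter(reps, .data$method == "IW", .data$replicate <= 6)$covered))
})

test_that("mean_density integrates to one and spikes on degenerate input", {
  md <- mean_density(study_small, methods = "IW")
  d_iw <- dplyr::filter(md, .data$method == "IW")
  dx <- diff(d_iw$x[1:2])
  expect_equal(sum(d_iw$density) * dx, 1, tolerance = .01)
  expect_true("true_scores" %in% md$method)

  fake <- study_small
  fake$replicates$estimate <- .42
  spike <- mean_density(fake, methods = "IW")
  expect_true(all(spike$x == .42))
})

test_that("attenuation ordering holds: averaging below hierarchical below truth", {
  gt <- make_ground_truth("two_task", rho = .7, tau = .5, I = 150L, L = 10L)
  st <- run_study(gt, priors = list(IW = prior_iw(s = .1)), n_replicates = 15L,
                  config = chain_config(n_burn = 500L, n_keep = 1000L),
                  base_seed = 310L)
  means <- st$replicates |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(m = mean(.data$estimate))
  m <- setNames(means$m, means$method)
  expect_lt(m[["average"]], m[["IW"]])
  expect_lt(m[["IW"]], .7 + .05)
})

test_that("inclusion pairing keeps the focal data identical across batteries", {
  gt8 <- make_ground_truth("eight_task", I = 40L, L = 6L)
  cfg <- chain_config(n_burn = 200L, n_keep = 400L)
  st2 <- run_study(gt8, priors = list(IW = prior_iw(s = .1)), n_replicates = 5L,
                   config = cfg, base_seed = 320L, tasks = c(1L, 2L))
  st8 <- run_study(gt8, priors = list(IW = prior_iw(s = .1)), n_replicates = 5L,
                   config = cfg, base_seed = 320L)
  sc <- inclusion_scatter(st2, st8)
  ts <- dplyr::filter(sc, .data$method == "true_scores")
  expect_equal(ts$estimate_marginal, ts$estimate_joint, tolerance = 1e-12)

  # identical configs on both axes: every point on the diagonal
  sc_same <- inclusion_scatter(st8, st8)
  expect_equal(sc_same$estimate_marginal, sc_same$estimate_joint)

  st_off <- run_study(gt8, priors = list(IW = prior_iw(s = .1)), n_replicates = 5L,
                      config = cfg, base_seed = 321L, tasks = c(1L, 2L))
  expect_error(inclusion_scatter(st_off, st8), "base seed")
})

test_that("manifest studies run end to end", {
  gt <- make_manifest_truth(J = 2, rho_pair = .5, I = 100L)
  st <- run_study(gt, priors = list(IW = prior_iw(s = 1)), n_replicates = 5L,
                  config = chain_config(n_burn = 200L, n_keep = 400L),
                  base_seed = 330L)
  expect_setequal(unique(st$replicates$method), c("true_scores", "pearson", "IW"))
  r <- dplyr::filter(st$replicates, .data$method == "IW")
  expect_true(all(abs(r$estimate - .5) < .3))
})

test_that("scale sweeps label rmse tables and study outputs serialize", {
  gt <- make_ground_truth("two_task", rho = .5, tau = .2, I = 40L, L = 6L)
  sw <- run_scale_sweep(gt, "iw", c(.05, .2), n_replicates = 4L,
                        config = chain_config(n_burn = 150L, n_keep = 300L),
                        base_seed = 340L)
  expect_setequal(unique(sw$s), c(.05, .2))
  expect_equal(nrow(sw), 2 * 2)  # (IW, average) x 2 scales

  dir <- withr::local_tempdir()
  write_study(study_small, dir)
  expect_true(all(file.exists(file.path(dir,
    c("replicates.csv", "rmse.csv", "coverage.csv", "config.yaml")))))
  back <- readr::read_csv(file.path(dir, "replicates.csv"), show_col_types = FALSE)
  expect_equal(nrow(back), nrow(study_small$replicates))
  expect_s3_class(autoplot(study_small), "ggplot")
  expect_s3_class(plot_coverage(study_small), "ggplot")
})
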