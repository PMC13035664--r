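test_that("identical seeds give bit-identical datasets", {
  gt <- make_ground_truth("two_task", rho = .4)
  expect_identical(sample_true_scores(gt, seed = 3), sample_true_scores(gt, seed = 3))
  th <- sample_true_scores(gt, seed = 3)
  expect_identical(sample_trials(gt, th, seed = 4), sample_trials(gt, th, seed = 4))
  expect_identical(simulate_experiment(gt, 5)$data, simulate_experiment(gt, 5)$data)
})

test_that("degenerate variances collapse to their means", {
  gt <- make_ground_truth("two_task", rho = .4, sigma = c(0, 0))
  th <- sample_true_scores(gt, seed = 1)
  expect_true(all(th[, 1] == .5) && all(th[, 2] == .5))

  gt2 <- make_ground_truth("two_task", tau = 0)
  th2 <- sample_true_scores(gt2, seed = 2)
  d <- sample_trials(gt2, th2, seed = 3)
  expect_equal(d$score, th2[cbind(d$individual, d$task)])
})

test_that("sampled true scores match the requested covariance", {
  gt <- make_ground_truth("two_task", rho = .5, I = 1e5L)
  th <- sample_true_scores(gt, seed = 10)
  expect_lt(abs(cor(th)[1, 2] - .5), .01)
  S <- cov(th)
  expect_true(all(abs(S / true_cov(gt) - 1) < .02))

  gt7 <- make_ground_truth("two_task", rho = .7)
  th7 <- sample_true_scores(gt7, seed = 11)
  expect_lt(abs(cor(th7)[1, 2] - .7), 3 * (1 - .49) / sqrt(200))
})

test_that("per-cell trial noise has SD tau", {
  gt <- make_ground_truth("two_task", rho = .3, I = 2L, L = 10000L)
  th <- sample_true_scores(gt, seed = 4)
  d <- sample_trials(gt, th, seed = 5)
  sds <- tapply(d$score, list(d$individual, d$task), sd)
  expect_true(all(abs(sds / .2 - 1) < .02))
})

test_that("contrast cells difference back to the slopes", {
  gt <- make_ground_truth("contrast", tau = 0, I = 25L, L = 4L)
  th <- sample_true_scores(gt, seed = 6)
  d <- sample_trials(gt, th, seed = 7)
  cell <- tapply(d$score, list(d$individual, d$task, d$condition), mean)
  expect_equal(unname(cell[, , 2] - cell[, , 1]), unname(th), tolerance = 1e-12)
})

test_that("manifest samples land near the target correlation", {
  gt <- make_manifest_truth(J = 2, rho_pair = .5, I = 200L)
  y <- sample_manifest(gt, seed = 8)
  expect_lt(abs(cor(y)[1, 2] - .5), 3 / sqrt(197))

  gt0 <- make_manifest_truth(J = 3, rho_pair = 0, rho_background = 0, I = 5000L)
  y0 <- sample_manifest(gt0, seed = 9)
  expect_true(all(abs(cor(y0)[upper.tri(diag(3))]) < .05))

  expect_error(sample_manifest(make_ground_truth("two_task")), "manifest")
})

test_that("trial data round-trip through long CSV", {
  gt <- make_ground_truth("contrast", I = 6L, L = 3L)
  d <- simulate_experiment(gt, 12)$data
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(d, path)
  expect_identical(readLines(path, n = 1L), "individual,task,condition,replicate,score")
  back <- read_trials(path)
  expect_equal(back$score, d$score)
  expect_equal(back[c("individual", "task", "condition", "replicate")],
               d[c("individual", "task", "condition", "replicate")],
               ignore_attr = TRUE)

  gth <- make_ground_truth("two_task", I = 5L, L = 2L)
  dh <- simulate_experiment(gth, 13)$data
  write_trials(dh, path)
  backh <- read_trials(path)
  expect_false("condition" %in% names(backh))
  expect_equal(backh$score, dh$score)
})
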