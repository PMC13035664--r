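# Replicate-level simulation harness: run a study (generate data once per
# replicate, fit every configured method on the identical data), then
# aggregate RMSE, interval coverage, and posterior-mean densities.

#' Calibrated default priors for a ground truth
#'
#' The calibrated setting matches each prior's scale to the generating
#' between-individual SD: `S = diag(sigma^2)` with `v = J + 1` for the
#' inverse Wishart, `s = sigma` for the scaled inverse Wishart (v = 2) and
#' the LKJ (eta = 1, half-t(2) scales).
#'
#' @param gt A [make_ground_truth()] object.
#' @return A named list of prior specs.
#' @export
default_priors <- function(gt) {
  s <- gt$sigma[1L]
  list(IW = prior_iw(s = s), SIW = prior_siw(s = s), LKJ = prior_lkj(s = s))
}

#' Run a replicate-level simulation study
#'
#' For each replicate `r`: seed the stream at `base_seed + r`, generate one
#' dataset from `gt`, fit every prior in `priors` on that same dataset, and
#' record posterior means and equal-tailed 95% credible intervals for every
#' correlation coefficient. Two reference methods are recorded alongside:
#' `true_scores` (the Pearson correlation of the latent true scores — the
#' best case achievable with I individuals) and `average` (the attenuated
#' averaging estimator with its Fisher interval).
#'
#' @param gt A [make_ground_truth()] object (any design).
#' @param priors Named list of prior specs; default [default_priors()].
#' @param n_replicates Number of replicate runs (default 100).
#' @param config A [chain_config()]; its seed is ignored (per-replicate
#'   seeds are derived from `base_seed`).
#' @param base_seed Base integer seed; replicate `r` uses `base_seed + r`
#'   for data and `base_seed + r + 5e5` for fitting.
#' @param conf.level Credible/confidence level (default .95).
#' @param tasks Optional subset of task ids to analyze. Data are generated
#'   from the full ground truth and then restricted, so a bivariate analysis
#'   with `tasks = c(1, 2)` sees exactly the same focal-pair data as the
#'   full-battery analysis with the same `base_seed` (the inclusion study's
#'   pairing). Task ids are renumbered to `seq_along(tasks)` but terms keep
#'   the original ids.
#' @param tolerate_failures If `TRUE`, a failing replicate is recorded and
#'   skipped; the default aborts.
#' @return A `study_result`: a list with the per-replicate tibble
#'   (`replicate`, `method`, `term`, `truth`, `estimate`, `conf.low`,
#'   `conf.high`, `covered`, `max_rhat`), the ground truth, and the
#'   configuration.
#' @export
run_study <- function(gt, priors = default_priors(gt), n_replicates = 100L,
                      config = chain_config(), base_seed = 1L,
                      conf.level = 0.95, tasks = NULL, tolerate_failures = FALSE) {
  validate_ground_truth(gt)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (is.null(names(priors)) || any(names(priors) == "")) {
    stop("priors must be a named list")
  }
  tasks <- tasks %||% seq_len(gt$J)
  sub_rho <- gt$rho[tasks, tasks, drop = FALSE]
  pairs <- which(upper.tri(sub_rho), arr.ind = TRUE)
  truth <- tibble::tibble(term = rho_name(tasks[pairs[, 1L]], tasks[pairs[, 2L]]),
                          truth = sub_rho[pairs])
  # fits see renumbered task ids; map their terms back to the original ids
  term_map <- setNames(truth$term, rho_name(pairs[, 1L], pairs[, 2L]))

  one_rep <- function(r) {
    seed_data <- base_seed + r
    sim <- simulate_experiment(gt, seed_data)
    if (length(tasks) < gt$J) {
      sim$theta <- sim$theta[, tasks, drop = FALSE]
      if (identical(gt$design, "manifest")) {
        sim$data <- sim$data[, tasks, drop = FALSE]
      } else {
        sim$data <- filter(sim$data, .data$task %in% tasks)
        sim$data$task <- match(sim$data$task, tasks)
      }
    }
    rows <- list()

    theta_mat <- sim$theta
    ct <- cor(theta_mat)
    rows$true <- tibble::tibble(
      method = "true_scores", term = truth$term,
      estimate = ct[pairs], conf.low = NA_real_, conf.high = NA_real_)

    design <- switch(gt$design, manifest = 0L, hierarchical = 1L, contrast = 2L)
    if (design == 0L) {
      stats <- list(I = nrow(sim$data), J = ncol(sim$data),
                    m = unname(sim$data), u = sd(sim$data))
      ci <- purrr::map2_dfr(pairs[, 1L], pairs[, 2L], function(a, b) {
        fisher_ci(ct[a, b], nrow(theta_mat), conf.level)
      })
      rows$pearson <- tibble::tibble(method = "pearson", term = truth$term,
                                     estimate = ci$estimate,
                                     conf.low = ci$conf.low, conf.high = ci$conf.high)
    } else {
      stats <- if (design == 1L) prepare_hier_data(sim$data) else
        prepare_contrast_data(sim$data)
      ca <- cor(stats$m)   # cell means (contrast: per-cell mean differences)
      ci <- purrr::map2_dfr(pairs[, 1L], pairs[, 2L], function(a, b) {
        fisher_ci(ca[a, b], stats$I, conf.level)
      })
      rows$avg <- tibble::tibble(method = "average", term = truth$term,
                                 estimate = ci$estimate,
                                 conf.low = ci$conf.low, conf.high = ci$conf.high)
    }

    for (pn in names(priors)) {
      cfg <- config
      cfg$seed <- base_seed + r + 500000L
      fit <- fit_from_stats(stats, priors[[pn]], cfg, design = design)
      td <- tidy(fit, conf.level = conf.level, parameters = "^rho_")
      td$term <- unname(term_map[td$term])
      rows[[pn]] <- tibble::tibble(method = pn, term = td$term,
                                   estimate = td$estimate,
                                   conf.low = td$conf.low, conf.high = td$conf.high,
                                   max_rhat = max(td$rhat, na.rm = TRUE))
    }
    out <- bind_rows(rows)
    out$replicate <- r
    out
  }

  reps <- vector("list", n_replicates)
  failures <- list()
  for (r in seq_len(n_replicates)) {
    if (tolerate_failures) {
      reps[[r]] <- tryCatch(one_rep(r), error = function(e) {
        failures[[length(failures) + 1L]] <<- list(replicate = r,
                                                   seed = base_seed + r,
                                                   message = conditionMessage(e))
        NULL
      })
    } else {
      reps[[r]] <- one_rep(r)
    }
  }
  replicates <- bind_rows(reps) |>
    left_join(truth, by = "term") |>
    mutate(covered = .data$truth >= .data$conf.low & .data$truth <= .data$conf.high) |>
    select(all_of(c("replicate", "method", "term", "truth", "estimate",
                    "conf.low", "conf.high", "covered")), dplyr::any_of("max_rhat"))

  structure(list(replicates = replicates, gt = gt, priors = priors,
                 config = config, base_seed = base_seed,
                 conf.level = conf.level, failures = failures),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %s '%s': %d replicates, methods: %s\n",
              x$gt$design, x$gt$preset, max(x$replicates$replicate),
              paste(unique(x$replicates$method), collapse = ", ")))
  print(rmse_table(x))
  invisible(x)
}

#' @export
tidy.study_result <- function(x, ...) x$replicates

#' @export
glance.study_result <- function(x, ...) {
  tibble::tibble(design = x$gt$design, preset = x$gt$preset,
                 n_replicates = max(x$replicates$replicate),
                 n_methods = length(unique(x$replicates$method)),
                 n_failures = length(x$failures),
                 base_seed = x$base_seed)
}

#' Root-mean-squared error of the point estimates
#'
#' RMSE of the posterior mean (or classical point estimate) per method and
#' coefficient, against one of two references:
#' * `"realized"` (default): each replicate's sample correlation among the
#'   I individuals' *true* scores. This treats the finite sample of people
#'   as given and asks how much accuracy is lost to trial noise — knowing
#'   the true scores exactly would give RMSE 0, and a method that recovers
#'   them perfectly attains the best case.
#' * `"population"`: the generating correlation `rho` itself, which folds
#'   the irreducible person-sampling noise (about `(1 - rho^2)/sqrt(I)`)
#'   into every method's RMSE.
#'
#' @param x A `study_result`.
#' @param reference `"realized"` or `"population"`.
#' @return A tibble: `method`, `term`, `truth`, `n`, `rmse`.
#' @export
rmse_table <- function(x, reference = c("realized", "population")) {
  stopifnot(inherits(x, "study_result"))
  reference <- match.arg(reference)
  if (length(unique(x$replicates$replicate)) < 2L) stop("need at least 2 replicates")
  reps <- x$replicates
  if (reference == "realized") {
    ref <- reps |>
      filter(.data$method == "true_scores") |>
      select(all_of(c("replicate", "term", "estimate"))) |>
      dplyr::rename(reference = "estimate")
    reps <- reps |>
      filter(.data$method != "true_scores") |>
      left_join(ref, by = c("replicate", "term"))
  } else {
    reps$reference <- reps$truth
  }
  reps |>
    group_by(.data$method, .data$term, .data$truth) |>
    summarise(n = dplyr::n(),
              rmse = sqrt(mean((.data$estimate - .data$reference)^2)),
              .groups = "drop")
}

#' Credible-interval coverage proportions
#'
#' Fraction of replicates whose interval contains the true correlation, per
#' method and coefficient.
#'
#' @param x A `study_result`.
#' @param first_n Restrict to the first `first_n` replicates.
#' @return A tibble: `method`, `term`, `truth`, `n`, `coverage`,
#'   `n_missed`.
#' @export
coverage_table <- function(x, first_n = NULL) {
  stopifnot(inherits(x, "study_result"))
  reps <- filter(x$replicates, !is.na(.data$covered))
  if (!is.null(first_n)) reps <- filter(reps, .data$replicate <= first_n)
  reps |>
    group_by(.data$method, .data$term, .data$truth) |>
    summarise(n = dplyr::n(), coverage = mean(.data$covered),
              n_missed = sum(!.data$covered), .groups = "drop")
}

#' Pooled coverage across methods, coefficients, and studies
#'
#' @param ... One or more `study_result` objects.
#' @param methods Methods to pool (default all Bayesian priors, i.e. every
#'   method except the classical references).
#' @param terms Optional coefficient names to pool.
#' @param first_n Restrict to the first `first_n` replicates of each study.
#' @return A single coverage proportion in `[0, 1]`.
#' @export
pooled_coverage <- function(..., methods = NULL, terms = NULL, first_n = NULL) {
  studies <- list(...)
  rows <- purrr::map_dfr(studies, function(s) {
    stopifnot(inherits(s, "study_result"))
    r <- filter(s$replicates, !is.na(.data$covered))
    if (is.null(methods)) {
      r <- filter(r, !.data$method %in% c("true_scores", "average", "pearson"))
    } else {
      r <- filter(r, .data$method %in% methods)
    }
    if (!is.null(terms)) r <- filter(r, .data$term %in% terms)
    if (!is.null(first_n)) r <- filter(r, .data$replicate <= first_n)
    r
  })
  mean(rows$covered)
}

#' Density of posterior means across replicates
#'
#' Gaussian-kernel density (Silverman bandwidth by default) of each method's
#' point estimates across replicates; the `true_scores` reference density is
#' included when present.
#'
#' @param x A `study_result`.
#' @param methods,term Which methods / coefficient to summarize (defaults:
#'   all methods, first coefficient).
#' @param bw Bandwidth passed to [stats::density()].
#' @param n Grid size.
#' @return A tibble: `method`, `term`, `x`, `density`.
#' @export
mean_density <- function(x, methods = NULL, term = NULL, bw = "nrd0", n = 512L) {
  stopifnot(inherits(x, "study_result"))
  reps <- x$replicates
  term <- term %||% reps$term[1L]
  reps <- filter(reps, .data$term == !!term)
  if (!is.null(methods)) reps <- filter(reps, .data$method %in% c(methods, "true_scores"))
  if (length(unique(reps$replicate)) < 10L) stop("need at least 10 replicates")
  purrr::map_dfr(split(reps, reps$method), function(d) {
    if (length(unique(d$estimate)) == 1L) {
      # degenerate: all mass at one value
      return(tibble::tibble(method = d$method[1L], term = term,
                            x = d$estimate[1L], density = Inf))
    }
    den <- density(d$estimate, bw = bw, n = n)
    tibble::tibble(method = d$method[1L], term = term, x = den$x, density = den$y)
  })
}

#' Paired bivariate-vs-multivariate estimates per replicate
#'
#' Joins two studies run with the same base seed (so the focal task pair's
#' data are identical) and pairs each replicate's estimate of the focal
#' correlation in isolation (`estimate_marginal`) with its estimate in the
#' larger battery (`estimate_joint`).
#'
#' @param bivariate,multivariate `study_result`s sharing `base_seed`.
#' @param term Focal coefficient (default `"rho_1_2"`).
#' @return A tibble: `replicate`, `method`, `estimate_marginal`,
#'   `estimate_joint`, plus a `"displacement"` attribute with the mean
#'   joint-minus-marginal difference per method.
#' @export
inclusion_scatter <- function(bivariate, multivariate, term = "rho_1_2") {
  stopifnot(inherits(bivariate, "study_result"), inherits(multivariate, "study_result"))
  if (bivariate$base_seed != multivariate$base_seed) {
    stop("studies must share the same base seed so replicates pair up")
  }
  b <- filter(bivariate$replicates, .data$term == !!term)
  m <- filter(multivariate$replicates, .data$term == !!term)
  out <- dplyr::inner_join(
    select(b, all_of(c("replicate", "method", "estimate"))),
    select(m, all_of(c("replicate", "method", "estimate"))),
    by = c("replicate", "method"), suffix = c("_marginal", "_joint"))
  disp <- out |>
    group_by(.data$method) |>
    summarise(displacement = mean(.data$estimate_joint - .data$estimate_marginal),
              .groups = "drop")
  attr(out, "displacement") <- disp
  out
}

#' Rerun a study across prior scale settings
#'
#' Repeats [run_study()] with one prior family rebuilt at each scale in
#' `s_values` (the scale-robustness sweep), binding RMSE tables with an `s`
#' column.
#'
#' @param gt A [make_ground_truth()] object.
#' @param family `"iw"`, `"siw"`, or `"lkj"`.
#' @param s_values Vector of scale settings.
#' @param ... Passed to [run_study()].
#' @return A tibble of [rmse_table()] rows with columns `s` prepended, plus
#'   the list of study results as the `"studies"` attribute.
#' @export
run_scale_sweep <- function(gt, family = c("iw", "siw", "lkj"), s_values, ...) {
  family <- match.arg(family)
  make <- switch(family, iw = prior_iw, siw = prior_siw, lkj = prior_lkj)
  studies <- purrr::map(s_values, function(s) {
    run_study(gt, priors = setNames(list(make(s = s)), toupper(family)), ...)
  })
  out <- purrr::map2_dfr(s_values, studies, function(s, st) {
    mutate(rmse_table(st), s = s, .before = 1L)
  })
  attr(out, "studies") <- studies
  out
}

#' Write a study's tables to a directory
#'
#' Writes `replicates.csv`, `rmse.csv`, `coverage.csv`, and `config.yaml`.
#'
#' @param x A `study_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(x, dir) {
  stopifnot(inherits(x, "study_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x$replicates, file.path(dir, "replicates.csv"))
  readr::write_csv(rmse_table(x), file.path(dir, "rmse.csv"))
  readr::write_csv(coverage_table(x), file.path(dir, "coverage.csv"))
  cfg <- list(preset = x$gt$preset, design = x$gt$design,
              I = x$gt$I, J = x$gt$J, L = x$gt$L,
              rho = as.vector(x$gt$rho), tau = x$gt$tau,
              priors = lapply(x$priors, function(p) p[setdiff(names(p), "S")]),
              n_burn = x$config$n_burn, n_keep = x$config$n_keep,
              n_chains = x$config$n_chains, base_seed = x$base_seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
autoplot.study_result <- function(object, term = NULL, ...) {
  reps <- object$replicates
  term <- term %||% reps$term[1L]
  reps <- filter(reps, .data$term == !!term)
  truth <- reps$truth[1L]
  ggplot2::ggplot(reps, ggplot2::aes(x = .data$method, y = .data$estimate)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = .4) +
    ggplot2::geom_hline(yintercept = truth, linetype = "dashed") +
    ggplot2::labs(y = paste("estimate of", term), x = NULL) +
    ggplot2::theme_minimal()
}

#' Interval plot of per-replicate credible intervals
#'
#' One horizontal interval per replicate and method, with non-covering
#' intervals highlighted.
#'
#' @param x A `study_result`.
#' @param term Coefficient to plot.
#' @param first_n Number of replicates to show (default 50).
#' @return A ggplot object.
#' @export
plot_coverage <- function(x, term = NULL, first_n = 50L) {
  reps <- x$replicates
  term <- term %||% reps$term[1L]
  reps <- filter(reps, .data$term == !!term, !is.na(.data$covered),
                 .data$replicate <= first_n)
  ggplot2::ggplot(reps, ggplot2::aes(y = .data$replicate)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$conf.low, xend = .data$conf.high,
                                       yend = .data$replicate,
                                       color = .data$covered)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$estimate), size = .6) +
    ggplot2::geom_vline(xintercept = reps$truth[1L], linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "grey50", `FALSE` = "red")) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = paste("95% interval for", term), y = "replicate") +
    ggplot2::theme_minimal()
}
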