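# Gridded prior visualization summaries: the marginal, joint, and
# conditional views of (sd, rho) and (rho, rho) that expose how each prior
# family couples variability with correlation.

#' Gridded prior-visualization summaries
#'
#' From a tibble of prior (or posterior) draws, computes:
#' (a) the normalized marginal histogram of a correlation coefficient;
#' (b) a 2-D density grid of (sd, rho);
#' (c) conditional histograms of rho given sd in the lowest / highest
#'     conditioning windows;
#' (d) a 2-D density grid of two correlation coefficients; and
#' (e) conditional histograms of one correlation given the other in its low /
#'     high windows.
#' Panels (d) and (e) are omitted when no second correlation column exists
#' (J = 2). All histograms integrate to 1.
#'
#' @param draws A tibble with one row per draw, e.g. from
#'   [prior_draws_tibble()].
#' @param rho_var,sd_var,rho2_var Column names of the focal correlation, the
#'   conditioning standard deviation, and the second correlation.
#' @param bins Number of histogram bins on `[-1, 1]` (default 61).
#' @param grid_bins Number of bins per axis in the 2-D grids.
#' @param window Tail probability of the low/high conditioning windows
#'   (default .2: bottom and top 20% quantiles).
#' @param sd_limit Upper display limit for the sd axis (default the 99%
#'   quantile, since heavy-tailed scale priors make the raw maximum useless).
#' @return An object of class `prior_panels`: a named list of tibbles.
#' @export
prior_panels <- function(draws, rho_var = "rho_1_2", sd_var = "sigma_1",
                         rho2_var = if ("rho_1_3" %in% names(draws)) "rho_1_3" else NULL,
                         bins = 61L, grid_bins = 40L, window = 0.2,
                         sd_limit = NULL) {
  draws <- as_tibble(draws)
  n <- nrow(draws)
  if (n < 1e4) stop("prior_panels() needs at least 10,000 draws; got ", n)
  rho <- draws[[rho_var]]
  sdv <- draws[[sd_var]]
  if (is.null(rho) || is.null(sdv)) stop("draws must contain columns ", rho_var, " and ", sd_var)
  sd_limit <- sd_limit %||% unname(quantile(sdv, .99))

  edges_rho <- seq(-1, 1, length.out = bins + 1L)
  panels <- list(
    marginal = hist_tibble(rho, edges_rho),
    joint_sd_rho = grid2d_tibble(pmin(sdv, sd_limit), rho,
                                 seq(0, sd_limit, length.out = grid_bins + 1L),
                                 seq(-1, 1, length.out = grid_bins + 1L),
                                 names = c("sd", "rho")),
    cond_sd_low = hist_tibble(rho[sdv <= quantile(sdv, window)], edges_rho),
    cond_sd_high = hist_tibble(rho[sdv >= quantile(sdv, 1 - window)], edges_rho)
  )
  if (!is.null(rho2_var)) {
    rho2 <- draws[[rho2_var]]
    panels$joint_rho_rho <- grid2d_tibble(rho, rho2,
                                          seq(-1, 1, length.out = grid_bins + 1L),
                                          seq(-1, 1, length.out = grid_bins + 1L),
                                          names = c("rho", "rho2"))
    panels$cond_rho_low <- hist_tibble(rho[rho2 <= quantile(rho2, window)], edges_rho)
    panels$cond_rho_high <- hist_tibble(rho[rho2 >= quantile(rho2, 1 - window)], edges_rho)
  }
  structure(panels, class = "prior_panels",
            vars = c(rho = rho_var, sd = sd_var, rho2 = rho2_var %||% NA_character_),
            window = window, n_draws = n)
}

# normalized histogram over fixed bin edges
hist_tibble <- function(x, edges) {
  x <- x[x >= edges[1] & x <= edges[length(edges)]]
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), length(edges) - 1L)
  width <- diff(edges)
  tibble::tibble(mid = (edges[-1] + edges[-length(edges)]) / 2,
                 width = width,
                 density = counts / (sum(counts) * width))
}

grid2d_tibble <- function(x, y, xedges, yedges, names = c("x", "y")) {
  keep <- x >= xedges[1] & x <= xedges[length(xedges)] &
    y >= yedges[1] & y <= yedges[length(yedges)]
  x <- x[keep]; y <- y[keep]
  ix <- findInterval(x, xedges, rightmost.closed = TRUE)
  iy <- findInterval(y, yedges, rightmost.closed = TRUE)
  nx <- length(xedges) - 1L; ny <- length(yedges) - 1L
  counts <- tabulate((iy - 1L) * nx + ix, nx * ny)
  area <- tcrossprod(diff(xedges), diff(yedges))
  dens <- matrix(counts, nx, ny) / (sum(counts) * area)
  out <- expand.grid(xm = (xedges[-1] + xedges[-length(xedges)]) / 2,
                     ym = (yedges[-1] + yedges[-length(yedges)]) / 2,
                     KEEP.OUT.ATTRS = FALSE)
  out$density <- as.vector(dens)
  names(out)[1:2] <- names
  tibble::as_tibble(out)
}

#' @export
print.prior_panels <- function(x, ...) {
  cat("<prior_panels> from", attr(x, "n_draws"), "draws; panels:",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize prior panels to CSV grids
#'
#' Writes one CSV per panel (`<prefix>_<panel>.csv`) with bin midpoints,
#' widths, and densities, so any plotting layer can render the views.
#'
#' @param panels A [prior_panels()] object.
#' @param prefix Path prefix for the CSV files.
#' @return The written file paths, invisibly.
#' @export
write_prior_panels <- function(panels, prefix) {
  stopifnot(inherits(panels, "prior_panels"))
  paths <- character(0)
  for (nm in names(panels)) {
    p <- paste0(prefix, "_", nm, ".csv")
    readr::write_csv(panels[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @export
autoplot.prior_panels <- function(object, ...) {
  marg <- dplyr::bind_rows(
    dplyr::mutate(object$marginal, panel = "marginal"),
    dplyr::mutate(object$cond_sd_low, panel = "rho | low sd"),
    dplyr::mutate(object$cond_sd_high, panel = "rho | high sd"))
  if (!is.null(object$cond_rho_low)) {
    marg <- dplyr::bind_rows(marg,
      dplyr::mutate(object$cond_rho_low, panel = "rho | low rho2"),
      dplyr::mutate(object$cond_rho_high, panel = "rho | high rho2"))
  }
  ggplot2::ggplot(marg, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_col(width = marg$width, fill = "grey35") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "correlation", y = "density") +
    ggplot2::theme_minimal()
}
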