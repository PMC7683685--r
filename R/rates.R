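#' Normalized unbinding-force histogram
#'
#' Bins rupture-force magnitudes into 1-pN bins starting at 0 and divides each
#' count by the total number of events N, so the bin values approximate the
#' probability mass of unbinding in each force bin.
#'
#' @param data a data frame with a `force_pN` column (e.g. primary events), or
#'   a bare numeric vector of force magnitudes (pN).
#' @param bin_width bin width, pN.
#' @return tibble with `bin_lo`, `bin_hi`, `count`, `prob`; attribute `n`
#'   holds N.
#' @examples
#' normalized_histogram(c(0.5, 1.5))
#' @export
normalized_histogram <- function(data, bin_width = 1) {
  x <- pull_numeric(data)
  if (length(x) == 0L) abort("cannot build a histogram from an empty force sample")
  if (any(!is.finite(x)) || any(x <= 0)) abort("forces must be positive finite magnitudes")
  edges <- seq(0, ceiling(max(x) / bin_width) * bin_width, by = bin_width)
  if (length(edges) < 2L) edges <- c(0, bin_width)
  counts <- graphics::hist(x, breaks = edges, plot = FALSE, right = FALSE)$counts
  out <- tibble(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1],
    count = counts, prob = counts / length(x)
  )
  attr(out, "n") <- length(x)
  out
}

#' Kernel density estimate of the unbinding-force distribution
#'
#' Gaussian kernel with boundary reflection at F = 0, evaluated on a regular
#' grid. The default bandwidth is Silverman's rule on the sample. Used to
#' stabilize the force-to-rate transform where events are sparse.
#'
#' @inheritParams normalized_histogram
#' @param bandwidth kernel bandwidth in pN, or `NULL` for Silverman's rule.
#' @param grid_step grid spacing, pN.
#' @param grid_max upper end of the grid; default `max(force) + 3*bandwidth`.
#' @param min_n minimum sample size accepted.
#' @return tibble with `force_pN` and `density`; attributes `bandwidth`, `n`.
#' @export
kde_pdf <- function(data, bandwidth = NULL, grid_step = 0.05, grid_max = NULL,
                    min_n = 10) {
  x <- pull_numeric(data)
  if (length(x) < min_n) {
    abort(sprintf("kernel density estimation needs at least %d forces, got %d", min_n, length(x)))
  }
  if (any(!is.finite(x)) || any(x <= 0)) abort("forces must be positive finite magnitudes")
  h <- bandwidth %||% stats::bw.nrd0(x)
  if (!is.numeric(h) || h <= 0) abort("`bandwidth` must be a positive number")
  grid_max <- grid_max %||% (max(x) + 3 * h)
  grid <- seq(0, grid_max, by = grid_step)
  dens <- reflected_kde(grid, x, h)
  out <- tibble(force_pN = grid, density = dens)
  attr(out, "bandwidth") <- h
  attr(out, "n") <- length(x)
  out
}

# Gaussian KDE with reflection at 0, evaluated at `grid`
reflected_kde <- function(grid, x, h) {
  K <- reflected_kernel_matrix(grid, x, h)
  as.vector(K %*% rep(1 / length(x), length(x)))
}

reflected_kernel_matrix <- function(grid, x, h) {
  outer(grid, x, function(g, xi) stats::dnorm(g, xi, h) + stats::dnorm(g, -xi, h))
}

#' Force-dependent unbinding rate from an unbinding-force sample
#'
#' Transforms a sample of primary unbinding forces from one condition and one
#' pulling direction into the force-dependent unbinding rate
#' \deqn{k(F) = r(F)\, \hat p(F) / \hat S(F),}
#' where \eqn{\hat p} is the reflected-kernel density estimate of the
#' rupture-force distribution, \eqn{\hat S(F) = 1 - \int_0^F \hat p} the
#' estimated survival, and \eqn{r(F)} the compliance-corrected effective
#' loading rate of the trap configuration. The curve is reported only for
#' forces at or above `f_min` (data below the experimental detection floor are
#' not interpretable) and while the estimated survival stays above
#' `survival_floor` (beyond that the transform is dominated by a handful of
#' events).
#'
#' @inheritParams kde_pdf
#' @param trap a [trap_config()] describing the pulling assay.
#' @param f_min lowest reported force, pN.
#' @param survival_floor stop reporting once \eqn{\hat S(F)} falls below this.
#' @return tibble of class `dyn_rate_curve` with `force_pN`, `rate_per_s`,
#'   `ci_lo`, `ci_hi` (NA until [boot_rate_ci()]), `survival`, `n_effective`;
#'   attributes `trap`, `bandwidth`, `n`, `direction`, `condition`.
#' @export
rate_curve <- function(data, trap, bandwidth = NULL, f_min = 0.5,
                       survival_floor = 0.05, grid_step = 0.05) {
  x <- pull_numeric(data)
  direction <- if (is.data.frame(data) && "direction" %in% names(data)) {
    unique(as.character(data$direction))
  } else "unspecified"
  if (length(direction) != 1L) {
    abort("`data` mixes pulling directions; compute rate curves per direction")
  }
  condition <- if (is.data.frame(data) && "condition" %in% names(data)) {
    paste(unique(as.character(data$condition)), collapse = "+")
  } else "unspecified"
  dens <- kde_pdf(x, bandwidth = bandwidth, grid_step = grid_step)
  h <- attr(dens, "bandwidth")
  S <- pmax(1 - cumtrapz(dens$force_pN, dens$density), 0)
  r <- effective_loading_rate(dens$force_pN, trap)
  keep <- dens$force_pN >= f_min & S >= survival_floor
  if (!any(keep)) {
    abort("estimated survival falls below `survival_floor` over the whole reporting grid",
          class = "dynforce_survival_floor")
  }
  out <- tibble(
    force_pN = dens$force_pN[keep],
    rate_per_s = r[keep] * dens$density[keep] / S[keep],
    ci_lo = NA_real_, ci_hi = NA_real_,
    survival = S[keep],
    n_effective = length(x) * S[keep]
  )
  class(out) <- c("dyn_rate_curve", class(out))
  attr(out, "trap") <- trap
  attr(out, "bandwidth") <- h
  attr(out, "n") <- length(x)
  attr(out, "f_min") <- f_min
  attr(out, "survival_floor") <- survival_floor
  attr(out, "direction") <- direction
  attr(out, "condition") <- condition
  out
}

#' KDE-free cumulative-hazard rate estimate
#'
#' Smoothing-free cross-check for [rate_curve()]: the Nelson-Aalen cumulative
#' hazard places an increment \eqn{1/(N - i + 1)} at each order statistic
#' \eqn{F_{(i)}}; its slope over force bins, multiplied by the effective
#' loading rate, is a piecewise-constant estimate of the unbinding rate.
#'
#' @inheritParams rate_curve
#' @param bin_width force bin width used to difference the cumulative hazard, pN.
#' @param min_n minimum sample size accepted.
#' @return tibble with `f_lo`, `f_hi`, `force_pN` (bin midpoint), `rate_per_s`,
#'   `n_at_risk`.
#' @export
empirical_rate_oracle <- function(data, trap, bin_width = 0.5, min_n = 50) {
  x <- sort(pull_numeric(data))
  n <- length(x)
  if (n < min_n) {
    abort(sprintf("the cumulative-hazard estimate needs at least %d forces, got %d", min_n, n))
  }
  r <- effective_loading_rate(0, trap)
  H <- cumsum(1 / (n - seq_len(n) + 1))
  edges <- seq(0, ceiling(max(x) / bin_width) * bin_width, by = bin_width)
  # cumulative hazard interpolated at bin edges (0 before the first event)
  H_edge <- stats::approx(c(0, x), c(0, H), xout = edges, method = "constant",
                          rule = 2, f = 0)$y
  at_risk <- vapply(edges[-length(edges)], function(e) sum(x > e), numeric(1))
  out <- tibble(
    f_lo = edges[-length(edges)], f_hi = edges[-1],
    force_pN = (edges[-1] + edges[-length(edges)]) / 2,
    rate_per_s = r * diff(H_edge) / diff(edges),
    n_at_risk = at_risk
  )
  filter(out, .data$n_at_risk > 0)
}
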