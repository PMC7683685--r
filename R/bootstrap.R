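# bootstrap resample means, computed in chunks to bound memory at large B
boot_means <- function(x, B) {
  n <- length(x)
  out <- numeric(B)
  chunk <- max(1L, min(B, as.integer(2e6 / n)))
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    idx <- sample.int(n, n * b, replace = TRUE)
    out[(done + 1L):(done + b)] <- .colMeans(x[idx], n, b)
    done <- done + b
  }
  out
}

#' Bootstrap confidence interval for a mean
#'
#' Percentile bootstrap of the sample mean (the default reporting convention
#' for unbinding-force means here: B = 4000 resamples, 95% level). A
#' bias-corrected and accelerated (BCa) interval is available behind
#' `method = "bca"`.
#'
#' @param x numeric sample, or a data frame with a `force_pN` column.
#' @param B number of bootstrap resamples (>= 1000).
#' @param level confidence level.
#' @param seed RNG seed for reproducible resampling.
#' @param method `"percentile"` (default) or `"bca"`.
#' @return a one-row tibble of class `dyn_ci`: `mean`, `lo`, `hi`, `level`,
#'   `B`, `n`, `method`.
#' @export
boot_ci_mean <- function(x, B = 4000, level = 0.95, seed = NULL,
                         method = c("percentile", "bca")) {
  method <- match.arg(method)
  x <- pull_numeric(x, what = "sample")
  n <- length(x)
  if (n < 5L) abort(sprintf("bootstrap CI needs a sample of at least 5 values, got %d", n))
  if (B < 1000L) abort("`B` must be at least 1000 resamples")
  m <- mean(x)
  alpha <- (1 - level) / 2
  means <- with_seed_if(seed, boot_means(x, B))
  if (method == "percentile") {
    q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 6)
  } else {
    z0 <- stats::qnorm(pmin(pmax(mean(means < m), 1 / B), 1 - 1 / B))
    jack <- (sum(x) - x) / (n - 1)
    d <- mean(jack) - jack
    a <- sum(d^3) / (6 * sum(d^2)^1.5)
    zl <- stats::qnorm(c(alpha, 1 - alpha))
    adj <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
    q <- stats::quantile(means, adj, names = FALSE, type = 6)
  }
  out <- tibble(
    mean = m, lo = min(q[1], m), hi = max(q[2], m),
    level = level, B = as.integer(B), n = n, method = method
  )
  class(out) <- c("dyn_ci", class(out))
  out
}

#' Shifted-null bootstrap test for a difference of means
#'
#' Implements the resampling test used to compare unbinding-force
#' distributions: B bootstrap means are drawn from each sample, subtracted
#' pairwise to form the sampling distribution of the difference of means, and
#' the distribution is recentred to zero (the null of equal means). The
#' two-tailed p-value `p_m` is the proportion of recentred differences at
#' least as large in magnitude as the observed difference of the original
#' means, floored at 1/B.
#'
#' @param a,b numeric samples (or data frames with a `force_pN` column).
#' @param B number of bootstrap means per sample (default 1e5).
#' @param seed RNG seed.
#' @param pairing `"paired"` subtracts the i-th mean of `a` from the i-th mean
#'   of `b` (B differences); `"cross"` uses the full cross-product of the two
#'   sets of means (only sensible for modest B).
#' @return one-row tibble of class `dyn_boot_test`: `p_m`, `observed_diff`,
#'   `B`, `n_a`, `n_b`.
#' @export
boot_mean_diff_test <- function(a, b, B = 1e5, seed = NULL,
                                pairing = c("paired", "cross")) {
  pairing <- match.arg(pairing)
  a <- pull_numeric(a, what = "sample a")
  b <- pull_numeric(b, what = "sample b")
  if (length(a) < 5L || length(b) < 5L) {
    abort("both samples need at least 5 values for the bootstrap mean-difference test")
  }
  if (pairing == "cross" && B > 20000L) {
    abort("`pairing = \"cross\"` forms B^2 differences; use B <= 20000")
  }
  obs <- mean(a) - mean(b)
  d <- with_seed_if(seed, {
    ma <- boot_means(a, B)
    mb <- boot_means(b, B)
    if (pairing == "paired") ma - mb else as.vector(outer(ma, mb, `-`))
  })
  shifted <- d - mean(d)
  p <- max(mean(abs(shifted) >= abs(obs)), 1 / B)
  out <- tibble(
    p_m = p, observed_diff = obs, B = as.integer(B),
    n_a = length(a), n_b = length(b), pairing = pairing
  )
  class(out) <- c("dyn_boot_test", class(out))
  out
}

#' Bootstrap confidence bands for a rate curve
#'
#' Resamples the unbinding forces with replacement, recomputes the
#' KDE-to-rate transform per resample on the point estimate's grid, and takes
#' pointwise percentile bands. The point estimate's bandwidth is held fixed
#' across resamples (Silverman's rule changes negligibly under resampling and
#' a fixed bandwidth lets the kernel matrix be reused). Resamples whose
#' estimated survival falls below the floor at a grid point are excluded
#' pointwise; the number of usable resamples per point is reported.
#'
#' @inheritParams rate_curve
#' @param B number of resamples.
#' @param level band level.
#' @param seed RNG seed.
#' @param min_n minimum sample size accepted.
#' @return the [rate_curve()] tibble with `ci_lo`, `ci_hi` filled in and an
#'   `n_boot_used` column.
#' @export
boot_rate_ci <- function(data, trap, B = 1000, level = 0.95, seed = NULL,
                         bandwidth = NULL, f_min = 0.5, survival_floor = 0.05,
                         grid_step = 0.05, min_n = 50) {
  x <- pull_numeric(data)
  n <- length(x)
  if (n < min_n) {
    abort(sprintf("rate-curve bootstrap needs at least %d forces, got %d", min_n, n))
  }
  pt <- rate_curve(data, trap, bandwidth = bandwidth, f_min = f_min,
                   survival_floor = survival_floor, grid_step = grid_step)
  h <- attr(pt, "bandwidth")
  # full KDE grid (the point estimate is a truncated view of it)
  grid <- seq(0, max(x) + 3 * h, by = grid_step)
  K <- reflected_kernel_matrix(grid, x, h)   # length(grid) x n
  W <- with_seed_if(seed, stats::rmultinom(B, n, rep(1 / n, n)))
  P <- K %*% W / n                            # densities per resample
  # survival per resample: trapezoid cumulative integral down the columns
  dg <- diff(grid)
  avg <- (P[-1, , drop = FALSE] + P[-nrow(P), , drop = FALSE]) / 2
  S <- 1 - apply(avg * dg, 2, cumsum)
  S <- rbind(rep(1, B), S)
  r <- effective_loading_rate(0, trap)
  Kmat <- r * P / S
  Kmat[S < survival_floor] <- NA_real_
  sel <- match(round(pt$force_pN / grid_step), round(grid / grid_step))
  Kmat <- Kmat[sel, , drop = FALSE]
  alpha <- (1 - level) / 2
  qs <- t(apply(Kmat, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE, names = FALSE, type = 6))
  pt$ci_lo <- pmin(qs[, 1], pt$rate_per_s)
  pt$ci_hi <- pmax(qs[, 2], pt$rate_per_s)
  pt$n_boot_used <- as.integer(rowSums(!is.na(Kmat)))
  attr(pt, "B") <- as.integer(B)
  attr(pt, "level") <- level
  # resampled rates on the reported grid; downstream segment classification
  # uses them for slope uncertainties
  attr(pt, "boot_rates") <- Kmat
  pt
}

#' Gaussian fit to a velocity histogram
#'
#' Bins single-molecule velocities and fits a Gaussian
#' `A * exp(-(v - mu)^2 / (2 sd^2))` to the bin counts by least squares, the
#' standard way single-molecule velocity histograms are summarized. The
#' reported SEM is the sample SD divided by sqrt(N); the plain sample mean is
#' included for comparison.
#'
#' @param v velocities (nm/s), or a data frame with a `velocity_nm_s` column.
#' @param bin_width histogram bin width, nm/s.
#' @return one-row tibble: `mean_fit`, `sd_fit`, `sem`, `sample_mean`,
#'   `sample_sd`, `n`.
#' @export
gaussian_velocity_fit <- function(v, bin_width = 10) {
  v <- pull_numeric(v, column = "velocity_nm_s", what = "velocities")
  n <- length(v)
  if (n < 20L) abort(sprintf("the Gaussian histogram fit needs at least 20 velocities, got %d", n))
  edges <- seq(floor(min(v) / bin_width) * bin_width,
               ceiling(max(v) / bin_width) * bin_width + bin_width, by = bin_width)
  hh <- graphics::hist(v, breaks = edges, plot = FALSE, right = FALSE)
  df <- data.frame(x = hh$mids, y = hh$counts)
  start <- list(A = max(df$y), mu = mean(v), s = stats::sd(v))
  fit <- tryCatch(
    stats::nls(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df, start = start,
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    mu_fit <- mean(v); sd_fit <- stats::sd(v)
  } else {
    cf <- stats::coef(fit)
    mu_fit <- unname(cf["mu"]); sd_fit <- abs(unname(cf["s"]))
  }
  tibble(
    mean_fit = mu_fit, sd_fit = sd_fit,
    sem = stats::sd(v) / sqrt(n),
    sample_mean = mean(v), sample_sd = stats::sd(v), n = n
  )
}

#' Welch's unpaired t test
#'
#' Thin wrapper around [stats::t.test()] (unequal variances, Satterthwaite
#' degrees of freedom) returning a tidy one-row tibble, with an explicit error
#' for degenerate zero-variance input.
#'
#' @param a,b numeric samples.
#' @return one-row tibble: `mean_a`, `mean_b`, `estimate`, `statistic`, `df`,
#'   `p_value`.
#' @export
welch_t_test <- function(a, b) {
  a <- pull_numeric(a, what = "sample a")
  b <- pull_numeric(b, what = "sample b")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(tibble(mean_a = mean(a), mean_b = mean(b), estimate = 0,
                    statistic = 0, df = NA_real_, p_value = 1))
    }
    abort("Welch's t test is undefined for two zero-variance samples with different means")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  tibble(
    mean_a = mean(a), mean_b = mean(b),
    estimate = mean(a) - mean(b),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

#' Stall-force summary
#'
#' Arithmetic mean and SD, the convention for reporting single-molecule stall
#' forces.
#'
#' @param forces stall forces (pN), or a data frame with a `stall_force_pN`
#'   column.
#' @return one-row tibble: `mean`, `sd`, `n`.
#' @export
stall_summary <- function(forces) {
  f <- pull_numeric(forces, column = "stall_force_pN", what = "stall forces")
  if (length(f) == 0L) abort("empty stall-force sample")
  tibble(mean = mean(f), sd = stats::sd(f), n = length(f))
}
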