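#' Reference unbinding-force profiles of the stalk registries
#'
#' Mean primary unbinding forces (with 95% CIs) of motor-domain constructs
#' whose stalk coiled-coil was disulfide cross-linked into a fixed registry,
#' measured in the apo state under the same constant-pulling assay. These are
#' the yardsticks against which a condition's unbinding-force sample is
#' classified: alpha (strong binding, backward load only), gamma
#' (intermediate), beta (weak). No forward-load alpha reference exists, so
#' forward classification draws on beta/gamma only.
#'
#' @return tibble with `label`, `direction`, `mean_pN`, `ci_lo`, `ci_hi`.
#' @export
registry_references <- function() {
  tibble(
    label = c("gamma", "gamma", "beta", "beta", "alpha"),
    direction = c("forward", "backward", "forward", "backward", "backward"),
    mean_pN = c(1.6, 1.6, 0.7, 0.7, 2.7),
    ci_lo = c(1.5, 1.6, 0.6, 0.7, 2.5),
    ci_hi = c(1.7, 1.7, 0.7, 0.8, 3.0)
  )
}

#' Assign stalk registries from unbinding-force samples
#'
#' Classifies the stalk-helix registry per pulling direction by comparing a
#' condition's primary unbinding forces with cross-linked reference profiles.
#'
#' Two modes, chosen by what the references carry:
#' * **raw-sample mode** (a `sample` list-column of numeric force vectors is
#'   present): each reference is compared with the condition by the
#'   shifted-null bootstrap mean-difference test; the call is the reference
#'   with the largest `p_m` among those with `p_m > alpha_level`.
#' * **mean-only mode** (default references): a reference is compatible when
#'   the bootstrap CI of the condition's mean overlaps the reference's stored
#'   CI (or contains the reference mean if no reference CI is stored); among
#'   compatible references the nearest mean wins. This summary-level check is
#'   weaker than the distribution-level test and is documented as such: it
#'   asks whether the two mean estimates are mutually consistent, not whether
#'   the distributions agree.
#'
#' If no reference is compatible the direction is labelled `"unassigned"`.
#'
#' @param forward,backward data frames with a `force_pN` column (>= 30 events
#'   each), forces as magnitudes.
#' @param refs reference table as in [registry_references()], optionally with
#'   a `sample` list-column of raw reference forces.
#' @param alpha_level compatibility threshold on `p_m` in raw-sample mode.
#' @param ci_level level of the condition's bootstrap CI used in mean-only
#'   mode.
#' @param B bootstrap resamples for CIs / tests.
#' @param seed RNG seed.
#' @param condition label carried into the call.
#' @return object of class `registry_call` with fields `condition`,
#'   `forward_label`, `backward_label`, `summary`
#'   ("backward/forward" in Greek, as registry tables are written),
#'   `details` (per-reference diagnostics tibble).
#' @export
classify_registry <- function(forward, backward, refs = registry_references(),
                              alpha_level = 0.05, ci_level = 0.95, B = 4000,
                              seed = NULL, condition = "unspecified") {
  fwd <- pull_numeric(forward)
  bwd <- pull_numeric(backward)
  if (length(fwd) < 30L || length(bwd) < 30L) {
    abort(sprintf(
      "registry classification needs >= 30 events per direction, got %d forward / %d backward",
      length(fwd), length(bwd)
    ))
  }
  refs <- as_tibble(refs)
  if (nrow(refs) < 2L) abort("`refs` must contain at least 2 references")
  if (!all(c("label", "direction", "mean_pN") %in% names(refs))) {
    abort("`refs` needs columns label, direction, mean_pN")
  }

  classify_dir <- function(x, dir, seed_offset) {
    rr <- refs[refs$direction == dir, , drop = FALSE]
    if (nrow(rr) == 0L) {
      return(list(label = "unassigned",
                  details = tibble(label = character(0))))
    }
    if ("sample" %in% names(rr) && any(vapply(rr$sample, function(s) length(s) > 0, logical(1)))) {
      p <- vapply(seq_len(nrow(rr)), function(i) {
        s <- rr$sample[[i]]
        if (length(s) < 5L) return(NA_real_)
        boot_mean_diff_test(x, s, B = B,
                            seed = if (is.null(seed)) NULL else seed + seed_offset + i)$p_m
      }, numeric(1))
      details <- tibble(label = rr$label, direction = dir, ref_mean_pN = rr$mean_pN,
                        p_m = p, compatible = !is.na(p) & p > alpha_level)
      lab <- if (any(details$compatible)) {
        details$label[which.max(ifelse(details$compatible, details$p_m, -Inf))]
      } else "unassigned"
    } else {
      ci <- boot_ci_mean(x, B = B, level = ci_level,
                         seed = if (is.null(seed)) NULL else seed + seed_offset)
      ref_lo <- if ("ci_lo" %in% names(rr)) rr$ci_lo else rr$mean_pN
      ref_hi <- if ("ci_hi" %in% names(rr)) rr$ci_hi else rr$mean_pN
      ref_lo <- ifelse(is.na(ref_lo), rr$mean_pN, ref_lo)
      ref_hi <- ifelse(is.na(ref_hi), rr$mean_pN, ref_hi)
      # published reference CIs are rounded to 0.1 pN and can end up one-sided
      # around the mean; use the larger half-width symmetrically
      ref_half <- pmax(ref_hi - rr$mean_pN, rr$mean_pN - ref_lo)
      compatible <- (rr$mean_pN + ref_half) >= ci$lo & (rr$mean_pN - ref_half) <= ci$hi
      details <- tibble(label = rr$label, direction = dir, ref_mean_pN = rr$mean_pN,
                        sample_mean_pN = ci$mean, ci_lo = ci$lo, ci_hi = ci$hi,
                        compatible = compatible)
      lab <- if (any(compatible)) {
        rr$label[compatible][which.min(abs(rr$mean_pN[compatible] - ci$mean))]
      } else "unassigned"
    }
    list(label = lab, details = details)
  }

  res_b <- classify_dir(bwd, "backward", 1000L)
  res_f <- classify_dir(fwd, "forward", 2000L)
  out <- structure(
    list(
      condition = condition,
      forward_label = res_f$label,
      backward_label = res_b$label,
      summary = paste0(greek_label(res_b$label), "/", greek_label(res_f$label)),
      details = bind_rows(res_b$details, res_f$details),
      n_forward = length(fwd), n_backward = length(bwd),
      mode = if ("sample" %in% names(refs)) "raw-sample" else "mean-only"
    ),
    class = "registry_call"
  )
  out
}

greek_label <- function(x) {
  switch(x, alpha = "α", beta = "β", gamma = "γ", x)
}

#' @export
print.registry_call <- function(x, ...) {
  cat(sprintf("<registry_call> %s: %s (backward/forward)\n", x$condition, x$summary))
  cat(sprintf("  backward: %s (n = %d), forward: %s (n = %d)\n",
              x$backward_label, x$n_backward, x$forward_label, x$n_forward))
  invisible(x)
}

#' Classify the bond phenotype of a rate curve
#'
#' Segments log k(F) versus F into up to `max_segments` linear pieces
#' (breakpoints found by a least-squares scan on a `break_grid`-spaced grid; an
#' extra segment is accepted only if it at least halves the residual sum of
#' squares) and labels each segment increasing, flat, or decreasing by whether
#' the slope's bootstrap confidence interval excludes zero. Curves from
#' [boot_rate_ci()] carry their resampled rates, and the slope uncertainty is
#' the spread of the segment slope across resamples; for plain curves it falls
#' back to an estimate from the confidence band (or `flat_tol` without one).
#' Adjacent segments with the same trend are merged, and the trend
#' pattern maps onto the bond phenotype: increasing = slip, flat = ideal,
#' decreasing = catch, with `slip-ideal` and `slip-ideal-slip` for the
#' composite patterns.
#'
#' @param curve a `dyn_rate_curve` spanning at least 2 pN.
#' @param slope_alpha two-sided level for calling a slope non-zero.
#' @param max_segments maximum number of linear segments (<= 3).
#' @param break_grid breakpoint scan spacing, pN.
#' @param min_span minimum segment span, pN.
#' @param sse_gain a k+1-segment fit is kept only if its SSE is below this
#'   fraction of the k-segment fit's.
#' @param flat_tol resolution floor: absolute log-slopes (1/pN) below this are
#'   called flat regardless of their nominal significance, because the KDE
#'   transform's bias produces reproducible structure of this size on truly
#'   force-independent bonds.
#' @return object of class `bond_phenotype`: `label`, `breakpoints` (pN),
#'   `segments` tibble (`f_lo`, `f_hi`, `slope`, `se`, `trend`).
#' @export
classify_bond_phenotype <- function(curve, slope_alpha = 0.05, max_segments = 3,
                                    break_grid = 0.25, min_span = 0.75,
                                    sse_gain = 0.5, flat_tol = 0.2) {
  if (!is.data.frame(curve) || !all(c("force_pN", "rate_per_s") %in% names(curve))) {
    abort("`curve` must be a rate curve with `force_pN` and `rate_per_s` columns")
  }
  keep <- is.finite(curve$rate_per_s) & curve$rate_per_s > 0
  Fg <- curve$force_pN[keep]
  y <- log(curve$rate_per_s[keep])
  span <- diff(range(Fg))
  if (length(Fg) < 10L || span < 2) {
    abort("the rate curve must span at least 2 pN of force to classify the bond phenotype")
  }
  has_band <- all(c("ci_lo", "ci_hi") %in% names(curve)) &&
    any(is.finite(curve$ci_lo[keep]) & curve$ci_lo[keep] > 0)
  sigma <- if (has_band) {
    s <- (log(curve$ci_hi[keep]) - log(pmax(curve$ci_lo[keep], 1e-12))) / (2 * stats::qnorm(0.975))
    mean(s[is.finite(s)])
  } else NA_real_
  h_eff <- attr(curve, "bandwidth") %||% 0.5

  sse_fit <- function(breaks) {
    bounds <- c(min(Fg), breaks, max(Fg))
    tot <- 0
    segs <- vector("list", length(bounds) - 1)
    for (i in seq_len(length(bounds) - 1)) {
      in_seg <- Fg >= bounds[i] & Fg <= bounds[i + 1]
      xf <- Fg[in_seg]; yf <- y[in_seg]
      if (length(xf) < 3L) return(NULL)
      fit <- stats::lm.fit(cbind(1, xf), yf)
      tot <- tot + sum(fit$residuals^2)
      segs[[i]] <- c(f_lo = bounds[i], f_hi = bounds[i + 1],
                     slope = unname(fit$coefficients[2]))
    }
    list(sse = tot, segments = segs)
  }

  candidate_breaks <- seq(ceiling((min(Fg) + min_span) / break_grid) * break_grid,
                          floor((max(Fg) - min_span) / break_grid) * break_grid,
                          by = break_grid)
  best <- list(`1` = sse_fit(numeric(0)))
  if (max_segments >= 2 && length(candidate_breaks) > 0) {
    fits2 <- purrr::map(candidate_breaks, ~ sse_fit(.x))
    ok <- !vapply(fits2, is.null, logical(1))
    if (any(ok)) best[["2"]] <- fits2[ok][[which.min(vapply(fits2[ok], `[[`, numeric(1), "sse"))]]
  }
  if (max_segments >= 3 && length(candidate_breaks) > 1) {
    pairs <- utils::combn(candidate_breaks, 2)
    pairs <- pairs[, pairs[2, ] - pairs[1, ] >= min_span, drop = FALSE]
    if (ncol(pairs) > 0) {
      fits3 <- purrr::map(seq_len(ncol(pairs)), ~ sse_fit(pairs[, .x]))
      ok <- !vapply(fits3, is.null, logical(1))
      if (any(ok)) best[["3"]] <- fits3[ok][[which.min(vapply(fits3[ok], `[[`, numeric(1), "sse"))]]
    }
  }
  chosen <- best[["1"]]
  for (k in c("2", "3")) {
    if (!is.null(best[[k]]) && best[[k]]$sse < sse_gain * chosen$sse) chosen <- best[[k]]
  }

  seg_tbl <- bind_rows(lapply(chosen$segments, function(s) as_tibble(as.list(s))))
  seg_tbl <- mutate(seg_tbl, span = .data$f_hi - .data$f_lo)
  z <- stats::qnorm(1 - slope_alpha / 2)
  boot_rates <- attr(curve, "boot_rates")
  boot_slope_se <- function(f_lo, f_hi) {
    if (is.null(boot_rates)) return(NA_real_)
    idx <- which(keep)[Fg >= f_lo & Fg <= f_hi]
    M <- boot_rates[idx, , drop = FALSE]
    full <- stats::complete.cases(M) & apply(M > 0, 1, all)
    if (sum(full) < 3L) return(NA_real_)
    X <- Fg[Fg >= f_lo & Fg <= f_hi][full]
    Y <- log(M[full, , drop = FALSE])
    xc <- X - mean(X)
    stats::sd(as.vector(crossprod(xc, Y)) / sum(xc^2))
  }
  seg_tbl$se <- vapply(seq_len(nrow(seg_tbl)), function(i) {
    se <- boot_slope_se(seg_tbl$f_lo[i], seg_tbl$f_hi[i])
    if (is.na(se) && has_band) {
      n_eff <- max(seg_tbl$span[i] / h_eff, 2)
      se <- sigma * sqrt(12) / (seg_tbl$span[i] * sqrt(n_eff))
    }
    se
  }, numeric(1))
  # a segment is flat when its slope is statistically indistinguishable from
  # zero OR below the resolution floor of the KDE transform (whose bias can
  # produce reproducible wiggles up to ~0.2 per pN, well under the log-slope
  # 1/F_scale >= 0.25 of any Bell slip scale reported for this system)
  seg_tbl$trend <- ifelse(
    abs(seg_tbl$slope) <= flat_tol |
      (!is.na(seg_tbl$se) & abs(seg_tbl$slope) <= z * seg_tbl$se),
    "flat", ifelse(seg_tbl$slope > 0, "up", "down")
  )

  # merge adjacent segments with the same trend
  keep_row <- c(TRUE, seg_tbl$trend[-1] != seg_tbl$trend[-nrow(seg_tbl)])
  grp <- cumsum(keep_row)
  merged <- seg_tbl |>
    mutate(grp = grp) |>
    group_by(.data$grp) |>
    summarise(
      f_lo = min(.data$f_lo), f_hi = max(.data$f_hi),
      slope = stats::weighted.mean(.data$slope, .data$span),
      se = mean(.data$se), trend = .data$trend[1], .groups = "drop"
    ) |>
    select(-"grp")

  pattern <- paste(merged$trend, collapse = ",")
  label <- switch(
    pattern,
    "up" = "slip", "flat" = "ideal", "down" = "catch",
    "up,flat" = "slip-ideal", "up,flat,up" = "slip-ideal-slip",
    "other"
  )
  breakpoints <- if (nrow(merged) > 1) merged$f_lo[-1] else numeric(0)
  structure(
    list(label = label, breakpoints = breakpoints, segments = merged,
         pattern = pattern),
    class = "bond_phenotype"
  )
}

#' @export
print.bond_phenotype <- function(x, ...) {
  cat(sprintf("<bond_phenotype> %s", x$label))
  if (length(x$breakpoints)) {
    cat(sprintf(" (breakpoints at %s pN)", paste(round(x$breakpoints, 2), collapse = ", ")))
  }
  cat("\n")
  print(as.data.frame(x$segments), row.names = FALSE)
  invisible(x)
}
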