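#' Piecewise Bell models of the force-dependent unbinding rate
#'
#' A bond model describes the instantaneous unbinding (hazard) rate \eqn{k(F)}
#' of a single motor-microtubule bond as a function of the magnitude of the
#' applied force. Each segment `[f_lo, f_hi)` follows a Bell law
#' \deqn{k(F) = k_0 \exp\{(F - F_{lo}) / F_{scale}\},}
#' where `f_scale = Inf` gives a force-independent ("ideal") segment and a
#' negative `f_scale` gives a rate that decreases with force (a catch-type
#' segment). With `continuous = TRUE` (the default) the `k0` of every segment
#' after the first is replaced by the rate at the end of the previous segment,
#' so \eqn{k(F)} is continuous; the stored `k0` column then reports the
#' effective values.
#'
#' @param segments data frame with columns `f_lo`, `f_hi`, `k0`, `f_scale`
#'   (forces in pN, rates in 1/s). Segments must be contiguous, non-overlapping
#'   and start at 0; the last `f_hi` may be `Inf`.
#' @param label free-text label, e.g. `"slip"` or `"slip-ideal"`.
#' @param continuous enforce continuity of \eqn{k(F)} across segment
#'   boundaries by propagating the boundary rate.
#' @return an object of class `bond_model`.
#' @examples
#' bond_slip(k0 = 1, f_scale = 2)
#' bond_model(tibble::tibble(
#'   f_lo = c(0, 2), f_hi = c(2, Inf), k0 = c(0.5, NA), f_scale = c(1, Inf)
#' ), label = "slip-ideal")
#' @export
bond_model <- function(segments, label = "custom", continuous = TRUE) {
  segments <- as_tibble(segments)
  req <- c("f_lo", "f_hi", "k0", "f_scale")
  if (!all(req %in% names(segments))) {
    abort(paste0("`segments` must have columns ", paste(req, collapse = ", ")))
  }
  segments <- arrange(segments, .data$f_lo)
  n <- nrow(segments)
  if (n < 1L) abort("a bond model needs at least one segment")
  if (segments$f_lo[1] != 0) abort("segments must cover forces starting at 0 pN")
  if (n > 1L && any(abs(segments$f_lo[-1] - segments$f_hi[-n]) > 1e-9)) {
    abort("segments must be contiguous and non-overlapping")
  }
  if (any(segments$f_hi <= segments$f_lo)) abort("each segment needs f_hi > f_lo")
  if (any(segments$f_scale == 0, na.rm = TRUE)) abort("`f_scale` must be non-zero (use Inf for an ideal segment)")
  if (!is.finite(segments$k0[1]) || segments$k0[1] < 0) {
    abort("the first segment needs a finite non-negative `k0`")
  }
  if (continuous && n > 1L) {
    for (i in 2:n) {
      segments$k0[i] <- segment_rate(
        segments$f_hi[i - 1L], segments$k0[i - 1L],
        segments$f_lo[i - 1L], segments$f_scale[i - 1L]
      )
    }
  } else if (any(!is.finite(segments$k0) | segments$k0 < 0)) {
    abort("all segments need finite non-negative `k0` when `continuous = FALSE`")
  }
  structure(
    list(segments = segments, label = label, continuous = continuous),
    class = "bond_model"
  )
}

segment_rate <- function(f, k0, f_lo, f_scale) {
  ifelse(is.infinite(f_scale), k0, k0 * exp(ifelse(is.infinite(f_scale), 0, (f - f_lo) / f_scale)))
}

#' @rdname bond_model
#' @param k0 unbinding rate at zero force (1/s).
#' @param f_scale force scale of the exponential (pN); the log-slope of
#'   \eqn{k(F)} is `1/f_scale`.
#' @export
bond_slip <- function(k0, f_scale) {
  stopifnot_scalar_number(k0, "k0", positive = TRUE)
  stopifnot_scalar_number(f_scale, "f_scale", positive = TRUE)
  bond_model(tibble(f_lo = 0, f_hi = Inf, k0 = k0, f_scale = f_scale), label = "slip")
}

#' @rdname bond_model
#' @export
bond_ideal <- function(k0) {
  stopifnot_scalar_number(k0, "k0", positive = TRUE)
  bond_model(tibble(f_lo = 0, f_hi = Inf, k0 = k0, f_scale = Inf), label = "ideal")
}

#' @rdname bond_model
#' @param f_break force (pN) at which the slip segment hands over to the ideal
#'   segment.
#' @export
bond_slip_ideal <- function(k0, f_scale, f_break = 2) {
  bond_model(
    tibble(
      f_lo = c(0, f_break), f_hi = c(f_break, Inf),
      k0 = c(k0, NA_real_), f_scale = c(f_scale, Inf)
    ),
    label = "slip-ideal"
  )
}

#' @rdname bond_model
#' @param f_break2 force (pN) at which the ideal segment hands back to a slip
#'   segment (for the slip-ideal-slip phenotype).
#' @param f_scale2 force scale of the upper slip segment (pN).
#' @export
bond_slip_ideal_slip <- function(k0, f_scale, f_break = 2, f_break2 = 5, f_scale2 = f_scale) {
  bond_model(
    tibble(
      f_lo = c(0, f_break, f_break2), f_hi = c(f_break, f_break2, Inf),
      k0 = c(k0, NA_real_, NA_real_), f_scale = c(f_scale, Inf, f_scale2)
    ),
    label = "slip-ideal-slip"
  )
}

#' @rdname bond_model
#' @export
bond_catch <- function(k0, f_scale) {
  stopifnot_scalar_number(k0, "k0", positive = TRUE)
  stopifnot_scalar_number(f_scale, "f_scale", positive = TRUE)
  bond_model(tibble(f_lo = 0, f_hi = Inf, k0 = k0, f_scale = -f_scale), label = "catch")
}

#' Evaluate the unbinding rate of a bond model
#'
#' @param bond a [bond_model()].
#' @param force force magnitudes (pN); negative values are an error, use
#'   magnitudes per direction.
#' @return unbinding rates (1/s), same length as `force`.
#' @export
bond_rate <- function(bond, force) {
  stopifnot(inherits(bond, "bond_model"))
  if (any(force < 0, na.rm = TRUE)) abort("`force` must be non-negative magnitudes")
  seg <- bond$segments
  idx <- findInterval(force, c(seg$f_lo, Inf), rightmost.closed = FALSE)
  idx[idx > nrow(seg)] <- nrow(seg)
  idx[idx < 1L] <- 1L
  segment_rate(force, seg$k0[idx], seg$f_lo[idx], seg$f_scale[idx])
}

# exact cumulative hazard divided by a constant loading rate r:
# H(F) = (1/r) * int_0^F k(f) df, piecewise analytic
bond_cumhaz <- function(bond, force, r) {
  seg <- bond$segments
  n <- nrow(seg)
  # integral of k over each full segment
  seg_int <- vapply(seq_len(n), function(i) {
    hi <- seg$f_hi[i]
    if (is.infinite(hi)) return(Inf)
    segment_haz_int(hi, seg$f_lo[i], seg$k0[i], seg$f_scale[i])
  }, numeric(1))
  cum_at_lo <- c(0, cumsum(seg_int))[seq_len(n)]
  idx <- findInterval(force, c(seg$f_lo, Inf))
  idx[idx > n] <- n
  idx[idx < 1L] <- 1L
  (cum_at_lo[idx] +
    segment_haz_int(force, seg$f_lo[idx], seg$k0[idx], seg$f_scale[idx])) / r
}

# int_{f_lo}^{f} k0 exp((u - f_lo)/fs) du, elementwise
segment_haz_int <- function(f, f_lo, k0, f_scale) {
  out <- ifelse(
    is.infinite(f_scale),
    k0 * (f - f_lo),
    k0 * f_scale * (exp((f - f_lo) / f_scale) - 1)
  )
  pmax(out, 0)
}

# invert H(F) = target (target in hazard units, already times 1/r applied by caller)
# used by the inverse-CDF sampler; target = -log(U) and we solve H(F)=target
bond_cumhaz_inverse <- function(bond, target, r) {
  seg <- bond$segments
  n <- nrow(seg)
  seg_int <- vapply(seq_len(n), function(i) {
    hi <- seg$f_hi[i]
    if (is.infinite(hi)) return(Inf)
    segment_haz_int(hi, seg$f_lo[i], seg$k0[i], seg$f_scale[i]) / r
  }, numeric(1))
  cum_at_lo <- c(0, cumsum(seg_int))[seq_len(n)]
  out <- numeric(length(target))
  for (j in seq_along(target)) {
    h <- target[j]
    i <- findInterval(h, cum_at_lo)
    i <- min(max(i, 1L), n)
    rem <- (h - cum_at_lo[i]) * r
    fs <- seg$f_scale[i]; k0 <- seg$k0[i]; f_lo <- seg$f_lo[i]
    if (is.infinite(fs)) {
      out[j] <- f_lo + rem / k0
    } else {
      arg <- 1 + rem / (k0 * fs)
      # catch segments (fs < 0) saturate: hazard integral is bounded by k0*|fs|
      out[j] <- if (arg <= 0) Inf else f_lo + fs * log(arg)
    }
  }
  out
}

#' @export
print.bond_model <- function(x, ...) {
  cat(sprintf("<bond_model: %s>\n", x$label))
  print(as.data.frame(x$segments), row.names = FALSE)
  invisible(x)
}
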