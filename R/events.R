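#' Detect binding/rupture events in a pulling trace
#'
#' Scans a uniformly sampled trace for binding-rupture episodes. A binding
#' onset is the first sample whose force magnitude exceeds `bind_threshold`
#' and stays loaded (above threshold, net rising) for at least
#' `min_bound_time`. Rupture is the sample where the force magnitude falls by
#' at least `drop_fraction` of the episode's running maximum within two
#' samples; the rupture force reported is the force at the last loaded samples
#' (identical to the running maximum on a monotone noiseless ramp, unbiased by
#' noise maxima otherwise). `F_start` is
#' the force magnitude at onset and defines the primary flag: a primary event
#' starts from baseline (`F_start <= bind_threshold`), a secondary event starts
#' under residual pre-load after a rebind. The pulling direction is the sign of
#' the force at rupture (positive = backward load).
#'
#' Events whose force never exceeds `report_floor` are discarded, matching the
#' reporting convention that only forces above the detection floor are
#' analyzed.
#'
#' @param trace a `dyn_trace` (or data frame with `time_s` and `force_pN`).
#' @param bind_threshold detection floor for binding, pN.
#' @param min_bound_time minimum bound duration for a real event, s.
#' @param drop_fraction fraction of the running maximum that must be lost
#'   within two samples to call a rupture.
#' @param report_floor discard events whose maximum force stays below this, pN.
#' @return tibble of class `dyn_events` with columns `t_bind_s`,
#'   `t_rupture_s`, `rupture_force_pN`, `F_start_pN`, `direction`,
#'   `is_primary`, sorted by time.
#' @export
detect_events <- function(trace, bind_threshold = 0.3, min_bound_time = 0.010,
                          drop_fraction = 0.8, report_floor = 0.5) {
  if (!is.data.frame(trace) || !all(c("time_s", "force_pN") %in% names(trace))) {
    abort("`trace` must be a data frame with `time_s` and `force_pN` columns")
  }
  t <- trace$time_s
  f <- trace$force_pN
  n <- length(t)
  if (n == 0L) return(empty_events())
  if (n > 2L) {
    dts <- diff(t)
    if (max(dts) - min(dts) > 1e-6 * stats::median(dts)) {
      abort("`trace` must be on a uniform time grid", class = "dynforce_nonuniform_trace")
    }
  }
  dt <- if (n > 1L) t[2] - t[1] else NA_real_
  w <- max(1L, as.integer(round(min_bound_time / dt)))
  a <- abs(f)

  ev_tb <- ev_tr <- ev_rf <- ev_fs <- numeric(0)
  ev_sgn <- numeric(0)

  i <- 1L
  onset <- NA_integer_
  f_start <- NA_real_
  run_max <- 0
  bound <- FALSE
  last_end <- 0L     # index where the previous episode ended
  post_min <- Inf

  while (i <= n) {
    if (!bound) {
      if (a[i] > bind_threshold) {
        # candidate onset: either a fresh crossing or a rebind during the
        # post-rupture relaxation (force still above threshold but rising again)
        start_ok <- TRUE
        j_end <- min(n, i + w)
        if (j_end > i) {
          # must stay above threshold/2 and end no lower than it started
          seg <- a[i:j_end]
          start_ok <- all(seg > bind_threshold / 2) && seg[length(seg)] >= seg[1] - 1e-12
        }
        if (start_ok) {
          bound <- TRUE
          onset <- i
          # the force at binding: the trace crosses the threshold only after
          # loading has begun, so walk back from the onset to the local force
          # minimum -- near baseline for a fresh binding, the relaxation dip
          # for a rebind under residual force. Stop once the backward walk
          # starts climbing the previous rupture's relaxation tail.
          f_start <- a[onset]
          j <- onset
          floor_j <- max(1L, last_end + 1L, onset - 4000L)
          while (j > floor_j) {
            j <- j - 1L
            if (a[j] < f_start) {
              f_start <- a[j]
            } else if (a[j] > f_start + bind_threshold / 2) {
              break
            }
          }
          run_max <- a[i]
        } else {
          i <- i + 1L
          next
        }
      }
      i <- i + 1L
    } else {
      if (a[i] > run_max) run_max <- a[i]
      lag2 <- a[max(onset, i - 2L)]
      # rupture: the force lost >= drop_fraction of the running maximum within
      # two samples (it is near baseline now but was still loaded at i - 2)
      if (a[i] <= (1 - drop_fraction) * run_max && lag2 >= 0.5 * run_max &&
          i - onset >= 1L) {
        # rupture force: the force at the last loaded samples. On a noiseless
        # monotone ramp this equals the running maximum exactly; on noisy data
        # it avoids the upward bias of a maximum taken over noise.
        if (run_max >= report_floor && (t[i] - t[onset]) >= min_bound_time) {
          ev_tb <- c(ev_tb, t[onset]); ev_tr <- c(ev_tr, t[i])
          ev_rf <- c(ev_rf, max(a[i - 1L], a[max(onset, i - 2L)]))
          ev_fs <- c(ev_fs, f_start)
          ev_sgn <- c(ev_sgn, sign(f[i - 1L]))
        }
        bound <- FALSE
        last_end <- i
        post_min <- a[i]
        run_max <- 0
        # skip ahead until the force either relaxes below threshold (fresh
        # baseline) or turns upward again (secondary rebind)
        i <- i + 1L
        while (i <= n && a[i] > bind_threshold && a[i] <= post_min + 1e-12) {
          post_min <- min(post_min, a[i])
          i <- i + 1L
        }
        next
      }
      if (a[i] < bind_threshold / 2) {
        # force wandered back to baseline without a sharp drop (e.g. the load
        # reversed at a sweep turnaround): end the episode without an event
        bound <- FALSE
        last_end <- i
        run_max <- 0
      }
      i <- i + 1L
    }
  }

  out <- tibble(
    t_bind_s = ev_tb, t_rupture_s = ev_tr,
    rupture_force_pN = ev_rf, F_start_pN = ev_fs,
    direction = ifelse(ev_sgn >= 0, "backward", "forward"),
    is_primary = ev_fs <= bind_threshold
  )
  out <- arrange(out, .data$t_bind_s)
  class(out) <- c("dyn_events", class(out))
  out
}

empty_events <- function() {
  out <- tibble(
    t_bind_s = numeric(0), t_rupture_s = numeric(0),
    rupture_force_pN = numeric(0), F_start_pN = numeric(0),
    direction = character(0), is_primary = logical(0)
  )
  class(out) <- c("dyn_events", class(out))
  out
}

#' Keep only primary events
#'
#' Primary events start from zero applied force; secondary events begin under
#' pre-load after a rebind and see a different force history, so downstream
#' rate estimation uses primary events only.
#'
#' @param events a `dyn_events` tibble (from [detect_events()] or
#'   [read_events()]).
#' @return the order-preserving subset with `is_primary == TRUE`.
#' @export
filter_primary <- function(events) {
  if (!is.data.frame(events) || !"is_primary" %in% names(events)) {
    abort("`events` must be a data frame with an `is_primary` column")
  }
  out <- events[which(events$is_primary), , drop = FALSE]
  if (!inherits(out, "dyn_events")) class(out) <- c("dyn_events", class(out))
  out
}
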