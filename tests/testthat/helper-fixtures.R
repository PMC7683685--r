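# shared fixtures: reference assay configs and bond constructors

# rigid-linkage trap at the reference assay settings (eff. rate = apparent = 5.6 pN/s)
trap_rigid <- function(...) trap_config(motor_stiffness = Inf, ...)

# mean rupture force implied by a bond/trap pair, by quadrature of the analytic pdf
analytic_mean_force <- function(bond, trap, f_max = 60) {
  g <- seq(0, f_max, by = 0.005)
  d <- analytic_force_pdf(bond, trap, g)$density
  sum(g * d) * 0.005
}

# slip bond whose mean rupture force under `trap` equals `mean_pN`
# (shape comparable to measured unbinding-force histograms)
bond_for_mean <- function(mean_pN, trap, f_scale = mean_pN / 2) {
  k0 <- stats::uniroot(
    function(k) analytic_mean_force(bond_slip(k, f_scale), trap) - mean_pN,
    c(1e-4, 1e4), tol = 1e-8
  )$root
  bond_slip(k0, f_scale)
}

# sweep turnaround times for a trap config (stage extrema)
turnaround_times <- function(trap, duration) {
  half <- trap$sweep_amplitude / trap$v_stage
  seq(half, duration, by = 2 * half)
}

# triangle-ramp trace builder for constructed detection fixtures:
# segments is a list of c(F_start, F_peak) ramps at `rate` pN/s separated by
# relaxation to baseline; returns a dyn_trace-like tibble
ramp_trace <- function(segments, rate = 5.6, sample_rate = 2000, gap_s = 0.5,
                       decay_per_sample = 0.15) {
  dt <- 1 / sample_rate
  f <- numeric(0)
  for (seg in segments) {
    gap <- rep(0, round(gap_s * sample_rate))
    n_ramp <- max(2L, ceiling((seg[2] - seg[1]) / (rate * dt)) + 1L)
    ramp <- seq(seg[1], seg[2], length.out = n_ramp)  # ends exactly at the peak
    # post-rupture exponential relaxation
    relax <- seg[2] * decay_per_sample^(1:8)
    f <- c(f, gap, ramp, relax)
  }
  f <- c(f, rep(0, round(gap_s * sample_rate)))
  tibble::tibble(
    time_s = seq_along(f) * dt,
    stage_nm = cumsum(rep(156 * dt, length(f))),
    force_pN = f
  )
}
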