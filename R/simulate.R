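#' Closed-form rupture-force distribution under constant pulling
#'
#' For a bond loaded at rate \eqn{r(F)} the rupture-force density is the
#' first-passage form
#' \deqn{p(F) = \frac{k(F)}{r(F)} \exp\left(-\int_0^F \frac{k(f)}{r(f)}\,df\right),}
#' evaluated here exactly for piecewise Bell models and the (force-independent)
#' effective loading rate of the linear-compliance trap model. This is the
#' analytic oracle against which both the direct sampler and the full trace
#' simulation are checked.
#'
#' @param bond a [bond_model()].
#' @param trap a [trap_config()]; only the effective loading rate enters.
#' @param f_grid force grid (pN) on which to evaluate the density.
#' @return tibble with columns `force_pN`, `density` (1/pN), `survival`.
#' @export
analytic_force_pdf <- function(bond, trap, f_grid = seq(0, 20, by = 0.01)) {
  r <- effective_loading_rate(f_grid, trap)
  if (any(r <= 0)) {
    abort("effective loading rate is zero; check `v_stage` and `motor_stiffness` in the trap config",
          class = "dynforce_zero_loading_rate")
  }
  H <- bond_cumhaz(bond, f_grid, r[1])
  tibble(
    force_pN = f_grid,
    density = bond_rate(bond, f_grid) / r * exp(-H),
    survival = exp(-H)
  )
}

#' @rdname analytic_force_pdf
#' @param q force quantiles (pN) at which to evaluate the CDF.
#' @return `analytic_force_cdf()`: the rupture-force CDF at `q`.
#' @export
analytic_force_cdf <- function(q, bond, trap) {
  r <- effective_loading_rate(0, trap)
  if (r <= 0) {
    abort("effective loading rate is zero; check `v_stage` and `motor_stiffness` in the trap config",
          class = "dynforce_zero_loading_rate")
  }
  out <- 1 - exp(-bond_cumhaz(bond, pmax(q, 0), r))
  out[q < 0] <- 0
  out
}

#' Draw rupture forces directly from the first-passage law
#'
#' Inverse-CDF sampling on the survival \eqn{S(F) = \exp(-\int_0^F k/r)},
#' exact for piecewise Bell models. Serves as the simulator-side oracle for
#' the full trace simulation and as a fast generator of unbinding-force
#' samples. Catch-dominated models have bounded cumulative hazard; draws that
#' would never rupture come back as `Inf` with a warning.
#'
#' @inheritParams analytic_force_pdf
#' @param n number of draws.
#' @param seed RNG seed (optional; the draw is reproducible given the seed).
#' @param direction,condition labels attached to the output.
#' @return tibble with column `force_pN` plus `direction` and `condition`.
#' @export
sample_unbinding_forces <- function(bond, trap, n, seed = NULL,
                                    direction = "backward", condition = "simulated") {
  stopifnot_scalar_number(n, "n", positive = TRUE)
  r <- effective_loading_rate(0, trap)
  if (r <= 0) {
    abort("effective loading rate is zero; check `v_stage` and `motor_stiffness` in the trap config",
          class = "dynforce_zero_loading_rate")
  }
  u <- with_seed_if(seed, stats::runif(n))
  f <- bond_cumhaz_inverse(bond, -log(u), r)
  if (any(is.infinite(f))) {
    warn(sprintf("%d of %d draws never rupture (bounded cumulative hazard); returned as Inf",
                 sum(is.infinite(f)), n))
  }
  tibble(force_pN = f, direction = direction, condition = condition)
}

#' Simulate a constant-pulling trap trace
#'
#' Emulates one bead/microtubule encounter series: the stage follows a
#' triangle wave of amplitude `sweep_amplitude` at speed `v_stage`; while the
#' motor is unbound the recorded force is zero-mean Gaussian noise (plus any
#' residual force relaxing with time constant `tau_relax_s`); binding occurs
#' as a Poisson event at rate `k_on`; while bound the force magnitude grows at
#' the effective loading rate with the sign set by the current sweep phase
#' (positive = backward load); rupture occurs stochastically with per-step
#' survival `exp(-k(|F|) dt)`. Rebinding before the force has relaxed to
#' baseline starts a secondary event with `F_start > 0`.
#'
#' The ground-truth event log (binding time, rupture time, force at rupture,
#' running maximum force, `F_start`, direction, primary flag) is attached as
#' attribute `"events"`; it is what detection is benchmarked against.
#'
#' @inheritParams analytic_force_pdf
#' @param duration trace length, s; must cover at least one sweep period.
#' @param seed RNG seed.
#' @param condition label stored in the trace metadata.
#' @param primary_tol forces at binding below this are logged as primary
#'   events (pN); matches the detection threshold default.
#' @return tibble of class `dyn_trace` with columns `time_s`, `stage_nm`,
#'   `force_pN`; attributes `trap`, `condition`, `events`.
#' @export
simulate_pull_trace <- function(trap, bond, duration, seed = NULL,
                                condition = "simulated", primary_tol = 0.3) {
  stopifnot(inherits(trap, "trap_config"), inherits(bond, "bond_model"))
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  r_app <- apparent_loading_rate(trap)
  if (trap$sample_rate < 10 * r_app) {
    abort(sprintf(
      "sample_rate = %g Hz is too low to resolve the loading: need >= 10 samples per pN at the apparent rate (%g pN/s), i.e. >= %g Hz",
      trap$sample_rate, r_app, 10 * r_app
    ), class = "dynforce_invalid_config")
  }
  period <- 4 * trap$sweep_amplitude / trap$v_stage
  if (duration < period) {
    abort(sprintf("`duration` (%g s) must cover at least one sweep period (%g s)", duration, period),
          class = "dynforce_invalid_config")
  }
  dt <- 1 / trap$sample_rate
  t <- seq(0, duration, by = dt)
  n <- length(t)

  # triangle wave: start at 0 moving +, turn at +A, back through 0 to -A, ...
  A <- trap$sweep_amplitude
  phase <- (trap$v_stage * t) %% (4 * A)
  stage <- ifelse(phase <= A, phase,
           ifelse(phase <= 3 * A, 2 * A - phase, phase - 4 * A))
  dirvec <- c(sign(diff(stage)), 0)
  dirvec[dirvec == 0] <- 1

  r_eff <- effective_loading_rate(0, trap)
  k_ser_dx <- r_eff * dt                      # force increment per sample while bound
  decay <- exp(-dt / trap$tau_relax_s)
  p_bind <- 1 - exp(-trap$k_on * dt)
  f_cap <- trap$k_trap * A

  rng <- with_seed_if(seed, list(
    u_bind = stats::runif(n),
    u_rup  = stats::runif(n),
    noise  = if (trap$noise_sd > 0) stats::rnorm(n, 0, trap$noise_sd) else numeric(n)
  ))

  # per-sample hazard lookup: k(|F|) tabulated on a fine force grid so the
  # sampling loop stays cheap
  k_step <- 0.002
  k_tab <- bond_rate(bond, seq(0, f_cap + k_step, by = k_step))
  p_rup_tab <- 1 - exp(-k_tab * dt)

  force <- numeric(n)
  bound <- FALSE
  f <- 0
  t_bind <- NA_real_; f_start <- NA_real_; f_max <- 0
  ev_tb <- ev_tr <- ev_rf <- ev_mf <- ev_fs <- numeric(0)
  ev_dir <- character(0)

  for (i in seq_len(n)) {
    if (!bound) {
      f <- f * decay
      if (rng$u_bind[i] < p_bind) {
        bound <- TRUE
        t_bind <- t[i]
        f_start <- abs(f)
        if (f_start < 1e-12) f <- 0
        f_max <- abs(f)
      }
    } else {
      f <- f + dirvec[i] * k_ser_dx
      if (f > f_cap) f <- f_cap
      if (f < -f_cap) f <- -f_cap
      af <- abs(f)
      if (af > f_max) f_max <- af
      if (rng$u_rup[i] < p_rup_tab[1L + as.integer(af / k_step + 0.5)]) {
        ev_tb <- c(ev_tb, t_bind); ev_tr <- c(ev_tr, t[i])
        ev_rf <- c(ev_rf, af); ev_mf <- c(ev_mf, f_max); ev_fs <- c(ev_fs, f_start)
        ev_dir <- c(ev_dir, if (f >= 0) "backward" else "forward")
        bound <- FALSE
      }
    }
    force[i] <- f + rng$noise[i]
  }

  events <- tibble(
    t_bind_s = ev_tb, t_rupture_s = ev_tr,
    rupture_force_pN = ev_rf, max_force_pN = ev_mf, F_start_pN = ev_fs,
    direction = ev_dir, is_primary = ev_fs <= primary_tol
  )
  out <- tibble(time_s = t, stage_nm = stage, force_pN = force)
  class(out) <- c("dyn_trace", class(out))
  attr(out, "trap") <- trap
  attr(out, "condition") <- condition
  attr(out, "events") <- events
  out
}

#' Gaussian motility and stall-force draws
#'
#' Fixtures for single-molecule velocity and stall-force summaries: velocities
#' and stall forces of individual motors are modelled as Gaussian with the
#' condition's mean and SD. Velocities can be truncated at zero (a motor is
#' scored only if it moves).
#'
#' @param n number of molecules.
#' @param mu,sigma mean and SD (nm/s for velocities, pN for stall forces).
#' @param seed RNG seed.
#' @param truncate_at_zero redraw non-positive velocities.
#' @return tibble with a `velocity_nm_s` (or `stall_force_pN`) column.
#' @export
simulate_velocities <- function(n, mu, sigma, seed = NULL, truncate_at_zero = TRUE) {
  stopifnot_scalar_number(n, "n", positive = TRUE)
  stopifnot_scalar_number(sigma, "sigma")
  if (sigma < 0) abort("`sigma` must be >= 0")
  v <- with_seed_if(seed, {
    x <- stats::rnorm(n, mu, sigma)
    if (truncate_at_zero && sigma > 0) {
      while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mu, sigma)
    }
    x
  })
  tibble(velocity_nm_s = v)
}

#' @rdname simulate_velocities
#' @export
simulate_stall_forces <- function(n, mu, sigma, seed = NULL) {
  stopifnot_scalar_number(n, "n", positive = TRUE)
  stopifnot_scalar_number(sigma, "sigma")
  if (sigma < 0) abort("`sigma` must be >= 0")
  f <- with_seed_if(seed, stats::rnorm(n, mu, sigma))
  tibble(stall_force_pN = f)
}
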