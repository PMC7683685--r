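#' Optical-trap and assay configuration
#'
#' Describes the constant-pulling assay: a bead in a harmonic trap of stiffness
#' `k_trap` while the stage sweeps back and forth parallel to the microtubule
#' at speed `v_stage`. The motor and its bead linkage act as a linear spring of
#' stiffness `motor_stiffness` in series with the trap, so the force on the
#' bond grows at the *effective* loading rate
#' \deqn{r = v_{stage} \, (1/k_{trap} + 1/k_{motor})^{-1} \le k_{trap} v_{stage},}
#' with equality only for a rigid linkage (`motor_stiffness = Inf`). The
#' apparent loading rate is `k_trap * v_stage`.
#'
#' Sign convention used throughout the package: positive force means backward
#' (hindering) load, negative force means forward (assisting) load.
#'
#' @param k_trap trap stiffness, pN/nm. The reference assay uses 0.036 pN/nm.
#' @param v_stage stage speed, nm/s (156 nm/s gives an apparent loading rate of
#'   5.6 pN/s at the reference stiffness).
#' @param sweep_amplitude half peak-to-peak stage excursion, nm.
#' @param motor_stiffness stiffness of the motor + linkage spring, pN/nm;
#'   `Inf` means a rigid linkage. Single motors are of order 0.1-1 pN/nm; the
#'   default 0.2 pN/nm is a typical value and is deliberately surfaced as an
#'   assumption (see the methods vignette).
#' @param k_on microtubule binding rate while unbound, 1/s.
#' @param sample_rate sampling rate of the recorded trace, Hz.
#' @param noise_sd white Gaussian force noise on the recorded trace, pN.
#' @param tau_relax_s time constant of the post-rupture force relaxation, s.
#'   Bead relaxation in the trap is fast compared to the sweep; the default
#'   0.25 ms means the force is back at baseline within one or two samples at
#'   2 kHz, while still allowing rebinding under residual force (secondary
#'   events) when `k_on` is large.
#' @param seed default seed stored with the config (simulation functions also
#'   take an explicit `seed`).
#' @return an object of class `trap_config`.
#' @examples
#' trap <- trap_config()
#' trap$k_trap * trap$v_stage       # apparent loading rate, pN/s
#' effective_loading_rate(0, trap)  # reduced by motor compliance
#' @export
trap_config <- function(k_trap = 0.036, v_stage = 156, sweep_amplitude = 800,
                        motor_stiffness = 0.2, k_on = 1, sample_rate = 2000,
                        noise_sd = 0.05, tau_relax_s = 2.5e-4, seed = NULL) {
  stopifnot_scalar_number(k_trap, "k_trap", positive = TRUE)
  stopifnot_scalar_number(v_stage, "v_stage", positive = TRUE)
  stopifnot_scalar_number(sweep_amplitude, "sweep_amplitude", positive = TRUE)
  stopifnot_scalar_number(motor_stiffness, "motor_stiffness", positive = TRUE, allow_inf = TRUE)
  stopifnot_scalar_number(k_on, "k_on")
  if (k_on < 0) abort("`k_on` must be >= 0", class = "dynforce_invalid_config")
  stopifnot_scalar_number(sample_rate, "sample_rate", positive = TRUE)
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0", class = "dynforce_invalid_config")
  stopifnot_scalar_number(tau_relax_s, "tau_relax_s", positive = TRUE)
  structure(
    list(
      k_trap = k_trap, v_stage = v_stage, sweep_amplitude = sweep_amplitude,
      motor_stiffness = motor_stiffness, k_on = k_on, sample_rate = sample_rate,
      noise_sd = noise_sd, tau_relax_s = tau_relax_s, seed = seed
    ),
    class = "trap_config"
  )
}

#' Loading rates of the constant-pulling assay
#'
#' The apparent loading rate is `k_trap * v_stage`; the effective (true)
#' loading rate on the bond accounts for the series compliance of the motor
#' and bead linkage and is never larger. For the linear motor spring used here
#' the effective rate is force-independent, but the force argument is kept so
#' force-dependent compliance models can slot in.
#'
#' @param force force magnitudes (pN) at which to evaluate the rate.
#' @param trap a [trap_config()].
#' @return loading rate(s), pN/s, recycled to `length(force)`.
#' @examples
#' trap <- trap_config(motor_stiffness = Inf)
#' effective_loading_rate(0, trap)  # equals the apparent rate 5.6 pN/s
#' @export
effective_loading_rate <- function(force, trap) {
  stopifnot(inherits(trap, "trap_config"))
  if (trap$k_trap <= 0) {
    abort("invalid config: `k_trap` must be positive", class = "dynforce_invalid_config")
  }
  if (trap$motor_stiffness <= 0) {
    abort("invalid config: `motor_stiffness` must be positive", class = "dynforce_invalid_config")
  }
  k_series <- if (is.infinite(trap$motor_stiffness)) {
    trap$k_trap
  } else {
    1 / (1 / trap$k_trap + 1 / trap$motor_stiffness)
  }
  rep(trap$v_stage * k_series, length.out = max(1L, length(force)))
}

#' @rdname effective_loading_rate
#' @export
apparent_loading_rate <- function(trap) {
  stopifnot(inherits(trap, "trap_config"))
  trap$k_trap * trap$v_stage
}

#' @export
print.trap_config <- function(x, ...) {
  cat("<trap_config>\n")
  cat(sprintf("  k_trap: %g pN/nm, v_stage: %g nm/s (apparent rate %.3g pN/s)\n",
              x$k_trap, x$v_stage, apparent_loading_rate(x)))
  cat(sprintf("  motor_stiffness: %g pN/nm -> effective rate %.3g pN/s\n",
              x$motor_stiffness, effective_loading_rate(0, x)))
  cat(sprintf("  sweep_amplitude: %g nm, k_on: %g 1/s, sample_rate: %g Hz, noise_sd: %g pN\n",
              x$sweep_amplitude, x$k_on, x$sample_rate, x$noise_sd))
  invisible(x)
}
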