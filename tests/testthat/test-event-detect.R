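test_that("a constructed noiseless ramp yields one primary event at its peak force", {
  tr <- ramp_trace(list(c(0, 3)))
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$rupture_force_pN, 3, tolerance = 1e-6)
  expect_lt(ev$F_start_pN, 0.01)
  expect_true(ev$is_primary)
  expect_equal(ev$direction, "backward")
})

test_that("a ramp resuming at 1 pN during relaxation is a secondary event", {
  # rupture from 3 pN, relaxation caught at ~1 pN by a rebind, loaded to 2.5 pN
  dt <- 1 / 2000
  ramp1 <- seq(0, 3, by = 5.6 * dt)
  relax <- 3 * 0.35^(1:2)               # decays through ~1 pN
  ramp2 <- seq(relax[2], 2.5, by = 5.6 * dt)
  relax2 <- 2.5 * 0.15^(1:8)
  f <- c(rep(0, 1000), ramp1, relax, ramp2, relax2, rep(0, 1000))
  tr <- tibble::tibble(time_s = seq_along(f) * dt, stage_nm = 0, force_pN = f)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 2)
  expect_true(ev$is_primary[1])
  expect_false(ev$is_primary[2])
  expect_equal(ev$F_start_pN[2], relax[2], tolerance = 0.05)
})

test_that("negative-force ramps are forward-direction events", {
  tr <- ramp_trace(list(c(0, 3)))
  tr$force_pN <- -tr$force_pN
  ev <- detect_events(tr)
  expect_equal(ev$direction, "forward")
})

test_that("detection tolerates a constant offset below half the threshold", {
  tr <- ramp_trace(list(c(0, 2), c(0, 3.5)))
  ev0 <- detect_events(tr)
  tr_off <- tr
  tr_off$force_pN <- tr$force_pN + 0.14
  ev1 <- detect_events(tr_off)
  expect_equal(nrow(ev1), nrow(ev0))
  expect_equal(ev1$rupture_force_pN, ev0$rupture_force_pN, tolerance = 0.15)
  expect_equal(ev1$is_primary, ev0$is_primary)
})

test_that("non-uniform grids error and empty traces give empty results", {
  tr <- ramp_trace(list(c(0, 2)))
  tr$time_s[10] <- tr$time_s[10] + 0.1
  expect_error(detect_events(tr), class = "dynforce_nonuniform_trace")
  empty <- tibble::tibble(time_s = numeric(0), stage_nm = numeric(0),
                          force_pN = numeric(0))
  expect_equal(nrow(detect_events(empty)), 0)
})

test_that("noiseless simulator ruptures are recovered to machine precision", {
  trap <- trap_config(motor_stiffness = Inf, noise_sd = 0, sweep_amplitude = 2000)
  b <- bond_slip(1, 1.5)
  tr <- simulate_pull_trace(trap, b, duration = 120, seed = 9)
  gt <- attr(tr, "events")
  gt <- gt[gt$max_force_pN >= 0.5, ]
  ev <- detect_events(tr)
  expect_equal(nrow(ev), nrow(gt))
  expect_equal(ev$rupture_force_pN, gt$max_force_pN, tolerance = 1e-12)
  # the drop is only visible at the sample after the rupture fired
  expect_lt(max(abs(ev$t_rupture_s - gt$t_rupture_s)), 2.5 / trap$sample_rate)
})

test_that("injected ruptures are recovered within 2 samples and 3*noise_sd on noisy traces", {
  trap <- trap_config(motor_stiffness = Inf)
  b <- bond_slip(1, 1.5)
  n_traces <- 25
  dur <- 42  # two sweep periods per trace
  checked <- 0L
  hits <- 0L
  for (i in seq_len(n_traces)) {
    tr <- simulate_pull_trace(trap, b, duration = dur, seed = 100 + i)
    gt <- attr(tr, "events")
    turns <- turnaround_times(trap, dur)
    clean <- vapply(seq_len(nrow(gt)), function(j) {
      gt$max_force_pN[j] >= 0.6 &&
        !any(turns >= gt$t_bind_s[j] - 0.05 & turns <= gt$t_rupture_s[j] + 0.05)
    }, logical(1))
    gt <- gt[clean, ]
    if (nrow(gt) == 0) next
    ev <- detect_events(tr)
    for (j in seq_len(nrow(gt))) {
      k <- which.min(abs(ev$t_rupture_s - gt$t_rupture_s[j]))
      ok <- length(k) == 1 &&
        abs(ev$t_rupture_s[k] - gt$t_rupture_s[j]) <= 2 / trap$sample_rate + 1e-9 &&
        abs(ev$rupture_force_pN[k] - gt$max_force_pN[j]) < 3 * trap$noise_sd
      checked <- checked + 1L
      hits <- hits + as.integer(isTRUE(ok))
    }
  }
  expect_gt(checked, 200)
  expect_gte(hits / checked, 0.99)
})

test_that("detected primary fractions track the simulator's own event log", {
  trap <- trap_config(motor_stiffness = Inf, k_on = 300)
  b <- bond_slip(1, 1.5)
  tr <- simulate_pull_trace(trap, b, duration = 150, seed = 5)
  gt <- attr(tr, "events")
  ev <- detect_events(tr)
  expect_gt(mean(!gt$is_primary), 0.01)  # secondaries actually occur
  expect_lt(abs(mean(!ev$is_primary) - mean(!gt$is_primary)), 0.05)
})

test_that("filter_primary is an order-preserving subset", {
  trap <- trap_config(motor_stiffness = Inf, k_on = 300)
  ev <- detect_events(simulate_pull_trace(trap, bond_slip(1, 1.5),
                                          duration = 60, seed = 6))
  prim <- filter_primary(ev)
  expect_true(all(prim$is_primary))
  expect_identical(prim$t_bind_s, sort(prim$t_bind_s))
  expect_identical(filter_primary(prim), prim)   # idempotent on all-primary input
  expect_equal(nrow(filter_primary(ev[0, ])), 0) # empty in, empty out
})
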