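test_that("normalized histogram uses 1-pN bins divided by N", {
  h <- normalized_histogram(c(0.5, 1.5))
  expect_equal(h$bin_lo, c(0, 1))
  expect_equal(h$prob, c(0.5, 0.5))
  h2 <- normalized_histogram(c(2.1, 2.2, 2.9))
  expect_equal(h2$prob[h2$bin_lo == 2], 1)
  expect_equal(sum(h2$prob), 1)
  expect_error(normalized_histogram(numeric(0)), "empty")
})

test_that("histogram bin masses match the analytic law within binomial error", {
  trap <- trap_rigid()
  b <- bond_slip(1, 1.5)
  n <- 1e4
  s <- sample_unbinding_forces(b, trap, n, seed = 21)
  h <- normalized_histogram(s)
  masses <- analytic_force_cdf(h$bin_hi, b, trap) - analytic_force_cdf(h$bin_lo, b, trap)
  se <- sqrt(masses * (1 - masses) / n)
  expect_true(all(abs(h$prob - masses) <= 3 * se + 1e-9))
})

test_that("reflected KDE is a proper density peaked at the data", {
  trap <- trap_rigid()
  s <- sample_unbinding_forces(bond_slip(1, 1.5), trap, 500, seed = 22)
  d <- kde_pdf(s)
  expect_true(all(d$density >= 0))
  mass <- sum(diff(d$force_pN) * (d$density[-1] + d$density[-nrow(d)]) / 2)
  expect_equal(mass, 1, tolerance = 1e-3)

  # repeated value with fixed bandwidth: maximum at the value
  d2 <- kde_pdf(rep(3, 20), bandwidth = 0.4)
  expect_equal(d2$force_pN[which.max(d2$density)], 3, tolerance = 0.05)

  expect_error(kde_pdf(c(1, 2, 3)), "at least 10")
  expect_error(kde_pdf(s, bandwidth = -1), "bandwidth")
})

test_that("KDE tracks the exponential density closely at n = 1e4", {
  trap <- trap_rigid()
  b <- bond_ideal(3.5)
  s <- sample_unbinding_forces(b, trap, 1e4, seed = 23)
  d <- kde_pdf(s)
  truth <- analytic_force_pdf(b, trap, d$force_pN)$density
  # away from the reflecting boundary the estimate stays within 5% of the peak
  away <- d$force_pN > 0.5
  expect_lt(max(abs(d$density - truth)[away]), 0.05 * max(truth))
})

test_that("ideal-bond rate curve is flat at r/mu", {
  trap <- trap_rigid()
  r <- effective_loading_rate(0, trap)
  k0 <- 3.5
  s <- sample_unbinding_forces(bond_ideal(k0), trap, 5000, seed = 7)
  rc <- rate_curve(s, trap)
  expect_true(all(rc$force_pN >= 0.5))
  expect_true(all(rc$survival >= 0.05 - 1e-12))
  expect_lt(max(abs(rc$rate_per_s - k0) / k0), 0.10)
})

test_that("slip-bond log-slope of the rate curve recovers 1/F_scale", {
  trap <- trap_rigid()
  f_scale <- 2
  s <- sample_unbinding_forces(bond_slip(1, f_scale), trap, 5000, seed = 8)
  rc <- rate_curve(s, trap)
  slope <- stats::coef(stats::lm(log(rate_per_s) ~ force_pN, data = rc))[2]
  expect_lt(abs(slope - 1 / f_scale) / (1 / f_scale), 0.15)
})

test_that("rate curve is linear in the loading rate and order-invariant", {
  trap <- trap_rigid()
  s <- sample_unbinding_forces(bond_slip(1, 1.5), trap, 800, seed = 9)
  rc1 <- rate_curve(s, trap)
  trap2x <- trap_config(v_stage = trap$v_stage * 2, motor_stiffness = Inf)
  rc2 <- rate_curve(s, trap2x)
  expect_equal(rc2$rate_per_s, 2 * rc1$rate_per_s, tolerance = 1e-12)

  shuffled <- s[sample.int(nrow(s)), ]
  rc3 <- rate_curve(shuffled, trap)
  expect_equal(rc3$rate_per_s, rc1$rate_per_s, tolerance = 1e-12)
})

test_that("survival is monotone non-increasing from 1 and mixed directions are refused", {
  trap <- trap_rigid()
  s <- sample_unbinding_forces(bond_slip(1, 1.5), trap, 500, seed = 10)
  rc <- rate_curve(s, trap)
  expect_true(all(diff(rc$survival) <= 1e-12))
  expect_lte(max(rc$survival), 1)
  mixed <- rbind(s, sample_unbinding_forces(bond_slip(1, 1.5), trap, 100,
                                            seed = 11, direction = "forward"))
  expect_error(rate_curve(mixed, trap), "direction")
})

test_that("cumulative-hazard oracle is flat for exponential forces and needs n >= 50", {
  trap <- trap_rigid()
  r <- effective_loading_rate(0, trap)
  k0 <- 3.5
  s <- sample_unbinding_forces(bond_ideal(k0), trap, 5000, seed = 12)
  orc <- empirical_rate_oracle(s, trap)
  core <- orc[orc$n_at_risk >= 100, ]
  expect_lt(stats::median(abs(core$rate_per_s - k0) / k0), 0.15)
  expect_error(empirical_rate_oracle(s[1:30, ], trap), "at least 50")
})

test_that("KDE transform and hazard oracle agree on a slip-bond sample", {
  trap <- trap_rigid()
  s <- sample_unbinding_forces(bond_slip(1, 1.5), trap, 5000, seed = 13)
  rc <- rate_curve(s, trap)
  orc <- empirical_rate_oracle(s, trap)
  k_at <- stats::approx(rc$force_pN, rc$rate_per_s, xout = orc$force_pN)$y
  ok <- !is.na(k_at) & orc$rate_per_s > 0
  expect_lt(stats::median(abs(k_at[ok] - orc$rate_per_s[ok]) / orc$rate_per_s[ok]), 0.15)
})
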