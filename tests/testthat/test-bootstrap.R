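test_that("bootstrap CI collapses for constant samples and matches the CLT half-width", {
  ci <- boot_ci_mean(rep(2.5, 30), B = 1000, seed = 1)
  expect_equal(c(ci$lo, ci$mean, ci$hi), rep(2.5, 3))

  x <- withr::with_seed(4, stats::rnorm(400))
  ci2 <- boot_ci_mean(x, B = 4000, seed = 2)
  half <- (ci2$hi - ci2$lo) / 2
  expect_lt(abs(half - 1.96 / sqrt(400)), 0.25 * 1.96 / sqrt(400))
  expect_true(ci2$lo <= ci2$mean && ci2$mean <= ci2$hi)

  expect_error(boot_ci_mean(c(1, 2, 3), B = 1000), "at least 5")
  expect_error(boot_ci_mean(x, B = 100), "at least 1000")
})

test_that("CI width shrinks roughly as 1/sqrt(n)", {
  x <- withr::with_seed(5, stats::rnorm(4000))
  w1 <- with(boot_ci_mean(x[1:500], B = 2000, seed = 3), hi - lo)
  w2 <- with(boot_ci_mean(x, B = 2000, seed = 3), hi - lo)
  expect_lt(abs(w1 / w2 - sqrt(8)), 0.25 * sqrt(8))
})

test_that("CI is reproducible given the seed and BCa stays ordered", {
  x <- withr::with_seed(6, stats::rexp(80))
  expect_identical(boot_ci_mean(x, B = 2000, seed = 9),
                   boot_ci_mean(x, B = 2000, seed = 9))
  bca <- boot_ci_mean(x, B = 2000, seed = 9, method = "bca")
  expect_true(bca$lo <= bca$mean && bca$mean <= bca$hi)
})

test_that("shifted-null bootstrap test hits its trivial endpoints", {
  cc <- rep(3, 10)
  expect_equal(boot_mean_diff_test(cc, cc, B = 1000, seed = 1)$p_m, 1)
  a <- withr::with_seed(7, stats::rnorm(100))
  b <- a + 10   # ten pooled SDs apart
  expect_equal(boot_mean_diff_test(a, b, B = 2000, seed = 2)$p_m, 1 / 2000)
  expect_error(boot_mean_diff_test(a[1:3], b, B = 1000), "at least 5")
})

test_that("p_m is symmetric in argument order and shift-invariant", {
  a <- withr::with_seed(8, stats::rnorm(60, 1))
  b <- withr::with_seed(9, stats::rnorm(60, 1.3))
  p_ab <- boot_mean_diff_test(a, b, B = 5000, seed = 3)$p_m
  p_ba <- boot_mean_diff_test(b, a, B = 5000, seed = 3)$p_m
  expect_equal(p_ab, p_ba, tolerance = 0.05)  # same resampling law, mirrored draws
  p_shift <- boot_mean_diff_test(a + 100, b + 100, B = 5000, seed = 3)$p_m
  expect_equal(p_shift, p_ab, tolerance = 1e-12)
})

test_that("rate-curve bootstrap bands contain the point estimate and the truth", {
  trap <- trap_rigid()
  k0 <- 3.5
  s <- sample_unbinding_forces(bond_ideal(k0), trap, 1000, seed = 11)
  rc <- boot_rate_ci(s, trap, B = 200, seed = 12)
  expect_true(all(rc$ci_lo <= rc$rate_per_s & rc$rate_per_s <= rc$ci_hi))
  expect_gte(mean(rc$ci_lo <= k0 & k0 <= rc$ci_hi), 0.90)
  rc_b <- boot_rate_ci(s, trap, B = 200, seed = 12)
  expect_identical(rc$ci_lo, rc_b$ci_lo)
  expect_error(boot_rate_ci(s[1:20, ], trap, B = 100), "at least 50")
})

test_that("velocity histogram Gaussian fit recovers the generating mean", {
  v <- simulate_velocities(284, mu = 110, sigma = 33.7, seed = 13)
  fit <- gaussian_velocity_fit(v)
  expect_lt(abs(fit$mean_fit - 110), 3 * 33.7 / sqrt(284))
  expect_equal(fit$sem, stats::sd(v$velocity_nm_s) / sqrt(284))
  expect_error(gaussian_velocity_fit(v$velocity_nm_s[1:10]), "at least 20")
})

test_that("Welch test returns p = 1 on identical samples and errors on degenerate input", {
  x <- withr::with_seed(14, stats::rnorm(40))
  expect_equal(welch_t_test(x, x)$p_value, 1)
  expect_error(welch_t_test(rep(1, 10), rep(2, 10)), "zero-variance")
  w <- welch_t_test(withr::with_seed(15, stats::rnorm(50, 110, 5)),
                    withr::with_seed(16, stats::rnorm(50, 11, 5)))
  expect_lt(w$p_value, 1e-10)
})

test_that("stall summary is the arithmetic mean and SD", {
  s <- stall_summary(c(4, 5))
  expect_equal(s$mean, 4.5)
  expect_equal(s$sd, stats::sd(c(4, 5)))
  expect_equal(s$n, 2)
})
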