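test_that("reference table orders binding strength alpha > gamma > beta backward", {
  refs <- registry_references()
  bwd <- refs[refs$direction == "backward", ]
  expect_gt(bwd$mean_pN[bwd$label == "alpha"], bwd$mean_pN[bwd$label == "gamma"])
  expect_gt(bwd$mean_pN[bwd$label == "gamma"], bwd$mean_pN[bwd$label == "beta"])
  expect_false("alpha" %in% refs$label[refs$direction == "forward"])
})

test_that("samples at the cross-linked reference means reproduce the known calls", {
  trap <- trap_rigid()
  mk <- function(mean_pN, seed) {
    sample_unbinding_forces(bond_for_mean(mean_pN, trap), trap, 300, seed = seed)
  }
  # weak binder both directions
  call_b <- classify_registry(mk(0.7, 1), mk(0.7, 2), seed = 1)
  expect_equal(call_b$summary, "β/β")
  # intermediate both directions
  call_g <- classify_registry(mk(1.6, 3), mk(1.6, 4), seed = 2)
  expect_equal(call_g$summary, "γ/γ")
  # strong backward, intermediate forward
  call_a <- classify_registry(mk(1.6, 5), mk(2.7, 6), seed = 3)
  expect_equal(call_a$summary, "α/γ")
  expect_equal(call_a$backward_label, "alpha")
  expect_equal(call_a$forward_label, "gamma")
})

test_that("classification is deterministic, reference-order invariant, and can refuse", {
  trap <- trap_rigid()
  fwd <- sample_unbinding_forces(bond_for_mean(1.6, trap), trap, 300, seed = 7)
  bwd <- sample_unbinding_forces(bond_for_mean(1.6, trap), trap, 300, seed = 8)
  c1 <- classify_registry(fwd, bwd, seed = 11)
  c2 <- classify_registry(fwd, bwd, seed = 11)
  expect_identical(c1$summary, c2$summary)
  refs_rev <- registry_references()[5:1, ]
  c3 <- classify_registry(fwd, bwd, refs = refs_rev, seed = 11)
  expect_identical(c3$summary, c1$summary)
  # a sample far from every reference is unassigned
  far <- sample_unbinding_forces(bond_for_mean(6, trap), trap, 300, seed = 9)
  c4 <- classify_registry(far, far, seed = 12)
  expect_equal(c4$forward_label, "unassigned")
  expect_equal(c4$backward_label, "unassigned")
  expect_error(classify_registry(fwd[1:10, ], bwd, seed = 1), ">= 30")
  expect_error(classify_registry(fwd, bwd, refs = registry_references()[1, ]),
               "at least 2")
})

test_that("raw-sample mode uses the bootstrap mean-difference test", {
  trap <- trap_rigid()
  b <- bond_for_mean(1.6, trap)
  refs <- registry_references()
  refs$sample <- lapply(seq_len(nrow(refs)), function(i) {
    sample_unbinding_forces(bond_for_mean(refs$mean_pN[i], trap), trap, 300,
                            seed = 20 + i)$force_pN
  })
  fwd <- sample_unbinding_forces(b, trap, 300, seed = 30)
  bwd <- sample_unbinding_forces(b, trap, 300, seed = 31)
  call <- classify_registry(fwd, bwd, refs = refs, B = 2000, seed = 32)
  expect_equal(call$mode, "raw-sample")
  expect_equal(call$summary, "γ/γ")
  expect_true(all(c("p_m", "compatible") %in% names(call$details)))
})

test_that("tidy/glance methods expose the call as tibbles", {
  trap <- trap_rigid()
  b <- bond_for_mean(0.7, trap)
  call <- classify_registry(
    sample_unbinding_forces(b, trap, 300, seed = 1),
    sample_unbinding_forces(b, trap, 300, seed = 2), seed = 3
  )
  td <- generics::tidy(call)
  expect_s3_class(td, "tbl_df")
  gl <- generics::glance(call)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$summary, call$summary)
})

test_that("bond phenotypes are recovered from simulated rate curves", {
  trap <- trap_rigid()
  # constant rate: ideal, no breakpoints
  si <- sample_unbinding_forces(bond_ideal(3.5), trap, 5000, seed = 40)
  ph_i <- classify_bond_phenotype(boot_rate_ci(si, trap, B = 150, seed = 41))
  expect_equal(ph_i$label, "ideal")
  expect_length(ph_i$breakpoints, 0)
  # monotone log-linear: slip
  ss <- sample_unbinding_forces(bond_slip(1, 1.5), trap, 5000, seed = 42)
  rc_s <- boot_rate_ci(ss, trap, B = 150, seed = 43)
  expect_equal(classify_bond_phenotype(rc_s)$label, "slip")
  # slip to 2 pN then ideal: breakpoint within 0.5 pN
  b_si <- bond_slip_ideal(k0 = 0.3, f_scale = 0.8, f_break = 2)
  s_si <- sample_unbinding_forces(b_si, trap, 5000, seed = 44)
  ph_si <- classify_bond_phenotype(boot_rate_ci(s_si, trap, B = 150, seed = 45))
  expect_equal(ph_si$label, "slip-ideal")
  expect_lt(abs(ph_si$breakpoints[1] - 2), 0.5)
})

test_that("phenotype labels are invariant to scaling the curve and catch is recognized", {
  trap <- trap_rigid()
  ss <- sample_unbinding_forces(bond_slip(1, 1.5), trap, 3000, seed = 46)
  rc <- boot_rate_ci(ss, trap, B = 150, seed = 47)
  rc10 <- rc
  rc10$rate_per_s <- rc$rate_per_s * 10
  rc10$ci_lo <- rc$ci_lo * 10
  rc10$ci_hi <- rc$ci_hi * 10
  expect_equal(classify_bond_phenotype(rc10)$label,
               classify_bond_phenotype(rc)$label)
  # synthetic decreasing curve: catch
  Fg <- seq(0.5, 6, by = 0.05)
  catch_curve <- tibble::tibble(
    force_pN = Fg, rate_per_s = 5 * exp(-Fg / 2),
    ci_lo = 4.5 * exp(-Fg / 2), ci_hi = 5.5 * exp(-Fg / 2)
  )
  expect_equal(classify_bond_phenotype(catch_curve)$label, "catch")
  expect_error(classify_bond_phenotype(catch_curve[1:20, ]), "2 pN")
})
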