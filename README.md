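# dynforce

Simulation and analysis of single-molecule optical-tweezers **constant-pulling
unbinding assays** for motor–microtubule bonds — the experiment in which a
bead carrying one motor domain (e.g. a dynein motor domain) is held in an
optical trap while the stage sweeps back and forth along a microtubule,
repeatedly loading the motor–microtubule bond until it ruptures. The package
is for single-molecule biophysicists who want to turn rupture-force
measurements into force-dependent unbinding rates, compare conditions with
bootstrap statistics, and read off bond phenotypes and stalk-registry
assignments — and for anyone who wants to test that pipeline against a
simulator with known ground truth.

## What it computes

The core transform converts the distribution of unbinding forces, measured
under a force ramp, into the bond's force-dependent unbinding (hazard) rate
without fitting any microscopic parameters:

```
k(F) = r(F) · p̂(F) / Ŝ(F),        Ŝ(F) = 1 − ∫₀^F p̂(f) df
```

where `p̂` is a boundary-reflected Gaussian KDE of the rupture-force
distribution and `r(F)` is the **effective loading rate** — the apparent rate
`k_trap · v_stage` (5.6 pN/s at the reference settings, 0.036 pN/nm ×
156 nm/s) reduced by the series compliance of the motor and its bead linkage,
modelled as a linear spring:

```
r = v_stage · (1/k_trap + 1/k_motor)⁻¹  ≤  k_trap · v_stage
```

Around this sit:

* a stochastic **assay simulator** (`simulate_pull_trace`,
  `sample_unbinding_forces`, `analytic_force_pdf`) with piecewise Bell bond
  models `k(F) = k₀ exp((F − F_lo)/F_scale)` covering slip, ideal, catch and
  composite bonds, plus exact first-passage sampling as an oracle;
* **event detection** (`detect_events`, `filter_primary`) that extracts
  binding→rupture events from traces and keeps only *primary* events
  (those starting from zero load, `F_start ≈ 0`);
* **bootstrap inference** (`boot_ci_mean`, `boot_rate_ci`,
  `boot_mean_diff_test`) — percentile CIs with B = 4000 resamples and the
  shifted-null two-tailed difference-of-means test with B = 10⁵ bootstrap
  means, p-value floored at 1/B;
* **classification** (`classify_registry`, `classify_bond_phenotype`) of
  stalk coiled-coil registries (α strong / γ intermediate / β weak binding)
  against cross-linked reference profiles, and of bond phenotypes
  (slip / ideal / slip-ideal / slip-ideal-slip / catch) by segmenting
  log k(F);
* motility summaries (`gaussian_velocity_fit`, `welch_t_test`,
  `stall_summary`) and a file/pipeline layer (`run_pipeline`, TSV traces,
  CSV events/forces, JSON reports, `inst/cli/dynforce`).

## Worked example

Simulate a γ-registry-like condition (slip bond, mean unbinding force
≈ 1.6 pN in both pulling directions) and run the full pipeline:

```r
library(dynforce)

trap <- trap_config(k_trap = 0.036, v_stage = 156, motor_stiffness = Inf)
bond <- bond_slip(k0 = 0.72, f_scale = 0.8)   # mean rupture force ~1.6 pN

forces <- dplyr::bind_rows(
  sample_unbinding_forces(bond, trap, 300, seed = 1, direction = "backward"),
  sample_unbinding_forces(bond, trap, 300, seed = 2, direction = "forward")
)

cfg <- list(
  trap = trap,
  analysis = list(bandwidth = NULL, f_min = 0.5, survival_floor = 0.05,
                  B_ci = 4000, B_rate = 500, alpha_level = 0.05, ci_level = 0.95),
  seeds = list(ci = 1, rates = 2, classify = 3),
  condition = list(label = "gamma-like demo")
)
res <- run_pipeline(cfg, forces = forces)

res$ci$backward
#>       mean      lo       hi level    B   n     method
#> 1 1.614386 1.53771 1.687079  0.95 4000 300 percentile

res$call
#> <registry_call> gamma-like demo: γ/γ (backward/forward)
#>   backward: gamma (n = 300), forward: gamma (n = 300)

head(res$rates$backward[, 1:4], 3)
#>   force_pN rate_per_s     ci_lo    ci_hi
#> 1     0.50   1.299975 0.9024271 1.688423
#> 2     0.55   1.363823 0.9573262 1.790020
#> 3     0.60   1.419548 1.0348238 1.870049

classify_bond_phenotype(res$rates$backward)
#> <bond_phenotype> slip
#>  f_lo f_hi   slope        se trend
#>   0.5 2.65 1.38642 0.2240795    up
```

Reading it: the backward-load mean unbinding force is 1.61 pN with a 95%
bootstrap CI [1.54, 1.69] — consistent with the γ (intermediate-strength)
registry reference (1.6 pN) and with no other, so the condition is called
γ/γ. The unbinding rate at 0.5 pN is ≈ 1.3 s⁻¹ and grows e-fold every
1/1.39 ≈ 0.7 pN of load; a single rising segment means a plain slip bond,
and the fitted log-slope 1.39 pN⁻¹ recovers the generating Bell scale
(1/0.8 = 1.25 pN⁻¹) within its uncertainty.

`autoplot(res$rates$backward)` draws the rate curve with its bootstrap band,
`plot_force_histogram(forces)` the 1-pN normalized histogram with the KDE
overlay, and `generics::tidy()` / `glance()` turn registry calls and
phenotypes into tibbles.

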