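# neonirs

Simulation tools for two linked questions in neonatal neuromonitoring:

1. **How small can a cerebral NIRS oximeter probe be?** Extremely preterm
   infants have heads a few centimetres across and fragile skin; a probe
   spanning 3.5 cm is a real burden, while one spanning ~1 cm would be easy
   to place — but shorter source–detector separations interrogate shallower
   tissue, and the estimate may end up reading the skin/scalp rather than
   the brain. `neonirs` models photon transport through a layered neonatal
   head, implements the spatially-resolved-spectroscopy (SRS) StO₂
   estimator that fielded oximeters use, and scores seven candidate probe
   geometries for responsiveness to the brain, bias, and robustness against
   saturation changes in the superficial layer.
2. **How large must a randomized trial of cerebral oximetry be?** The
   package computes analytic sample sizes for continuous and binary
   endpoints, inflates for attrition, and verifies the analytic power by
   simulating complete trials.

## The models in brief

**Forward model.** Weighted-packet Monte Carlo (MCML-style) in a stack of
homogeneous layers over a semi-infinite base: exponential steps in μt,
absorption-weighted packet attenuation, Henyey–Greenstein scattering,
Fresnel reflection/refraction at index mismatches, Russian roulette,
annular detection with per-layer partial pathlengths. Layer absorption is
μa(λ) = ln10·(ε_HbO₂[HbO₂] + ε_HHb[HHb]) + f_w·μa,water(λ); reduced
scattering is linear in wavelength. A closed-form diffusion dipole solution
(extrapolated boundary) serves as an independent cross-check and fast
forward model.

**Estimator.** SRS: per wavelength, the slope of attenuation
A = −log₁₀R across the two source–detector distances gives a scaled
absorption k·μa = (ln10·slope − 2/ρ̄)²/(3μs′); solving
k·μa(λ) = ln10·(ε_HbO₂x + ε_HHbyy) by least squares yields
StO₂ = 100·x/(x+y), with the unknown scale k cancelling. The inversion
uses haemoglobin only — ignoring water exactly as the instruments do — so
the forward model's water content exposes the estimator's bias.

**Trial power.** n per group = 2(z₁₋α/₂ + z_power)²(σ/δ)² (normal
approximation; exact noncentral-t solver available), pooled two-proportion
formula for binary endpoints, ceiling-based attrition inflation, and
empirical power from simulated trials with exact binomial CIs.

## Worked example

Trial design for a 5-point effect on a cognitive scale with SD 15:

```r
library(neonirs)
n_per_group_continuous(delta = 5, sd = 15, alpha = 0.05, power = 0.90)
#> Sample size (continuous endpoint, normal): delta 5, sd 15, alpha 0.05, power 0.9
#>   n per group: 190 (unrounded 189.13); total: 380
cohens_d(5, 15)$d_rounded
#> [1] 0.33
inflate_for_attrition(190, 0.20)
#> [1] 238
emp <- simulate_power(190, delta = 5, sd = 15, n_reps = 1e4, seed = 3)
emp$power; emp$ci
#> [1] 0.9023
#> [1] 0.8963130 0.9080515
```

190 evaluable infants per group are needed; with 20% mortality, 238 must be
randomized per group; 10,000 simulated trials at that size reject the null
90.2% of the time, confirming the analytic 90%.

Probe-design evaluation (runs the Monte Carlo experiment; ~15 min):

```r
p <- make_neonatal_preset()
ex <- run_design_experiment(p$medium, p$table,
        settings = transport_settings(n_photons = 2e5, max_pathlength = 600,
                                      detector_half_width = 1.0))
ex$metrics
#>   design_id responsiveness responsiveness_se bias_at_70 skin_sensitivity brain_mpp_fraction
#> 1         1          0.343          0.005310       1.42            16.16              0.241
#> 2         2          0.432          0.004993       4.46            13.92              0.293
#> 3         3          0.630          0.003353       2.76             8.96              0.411
#> 4         4          0.650          0.002581      12.69             6.51              0.466
#> 5         5          0.734          0.000432       3.14             4.83              0.529
#> 6         6          0.743          0.001657       3.36             3.32              0.603
#> 7         7          0.847          0.000913      -3.54             2.44              0.662
```

Reading: every design responds to brain SO₂ (responsiveness > 0, rising
with separation); the brain's share of the detected photon path grows from
0.24 to 0.66 across the designs; and the shortest designs are by far the
most sensitive to the skin/scalp — a 40-percentage-point skin-saturation
swing moves their StO₂ reading by ~14–16 points, versus ~2–5 for the three
longest designs. Bias values at the operating point carry several points of
Monte Carlo noise at the far designs (see `sto2_sd` in the sweep tables).
The mid-range designs offer most of the skin robustness of the longest
probe at roughly half its footprint.

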