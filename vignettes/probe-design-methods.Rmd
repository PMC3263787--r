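---
title: "Methods: simulating NIRS probe designs for the preterm brain and powering a trial of cerebral oximetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating NIRS probe designs for the preterm brain and powering a trial of cerebral oximetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`neonirs` answers two questions that arise when planning continuous
cerebral-oxygenation monitoring for extremely preterm infants. First, how
close together may the source and detector of a spatially-resolved NIRS
oximeter sit — so that the probe fits a tiny head — before the estimate
stops tracking the brain and starts tracking the skin? Second, how large
must a randomized trial be to demonstrate that such monitoring improves
neurodevelopmental outcome? The package contains a forward model of light
transport in layered tissue, the oximetry estimator itself, an experiment
harness that evaluates candidate probe geometries, and the trial-design
calculators.

## The tissue model

Tissue is an ordered stack of homogeneous layers over a semi-infinite
deepest layer; the design experiments use two layers, a combined
skin/scalp(+skull) superficial layer over brain. Each layer's absorption is
built from three chromophores,

$$\mu_a(\lambda) = \ln 10\left(\varepsilon_{HbO_2}(\lambda)\,[HbO_2] +
\varepsilon_{HHb}(\lambda)\,[HHb]\right) + f_{w}\,\mu_{a,water}(\lambda),$$

with $[HbO_2] = c_{Hb}\,SO_2/100$ and $[HHb] = c_{Hb}(1 - SO_2/100)$. The
extinction coefficients are stored as decadic values (the convention of the
published haemoglobin compilations) and converted by the explicit
$\ln 10$ factor — the classic source of silent factor-2.303 errors, so the
conversion lives in exactly one place, `mua()`. Reduced scattering follows
the linear model $\mu_s'(\lambda) = \mu_{s,\mathrm{ref}}'\,(1 -
b(\lambda - \lambda_\mathrm{ref}))$ that the oximetry algorithm itself
assumes.

The default head preset (`make_neonatal_preset()`) targets a neonate of
about 30–31 weeks gestation. No authoritative set of optical constants
exists for that population, so the preset is an implementer-chosen,
literature-plausible set, stated once and overridable through the
constructors or the YAML config:

| parameter | superficial | brain | unit |
|---|---|---|---|
| thickness | 4 | $\infty$ | mm |
| total haemoglobin | 60 | 50 | µM |
| SO₂ (starting) | 70 | 70 | % |
| water fraction | 0.70 | 0.85 | — |
| $\mu_s'$ at 760 nm | 1.4 | 0.7 | mm⁻¹ |
| scattering slope $b$ | 6.3e-4 | 6.3e-4 | nm⁻¹ |
| $g$, $n$ | 0.9, 1.4 | 0.9, 1.4 | — |

Wavelengths are 760 and 850 nm, straddling the haemoglobin isosbestic
point. A 4 mm superficial layer treats skin/scalp and skull as one optical
compartment; in an infant of this maturity each is only a few millimetres
thick, and the two have too-similar optical properties for a transport
model of this resolution to separate them usefully. Ship-your-own values
via `write_medium_config()`/`read_medium_config()` if you disagree — the
experiment harness takes the medium as data, not as doctrine.

## The photon Monte Carlo engine

`run_transport()` is a weighted-packet (MCML-style) Monte Carlo: a pencil
beam enters normally at the origin; packets take steps $s = -\ln u/\mu_t$,
deposit the fraction $\mu_a/\mu_t$ of their weight at each collision,
scatter through the Henyey–Greenstein phase function with the layer's $g$,
and undergo Fresnel reflection/refraction at every refractive-index
mismatch (including total internal reflection at the tissue–air surface,
which is what makes long diffuse paths possible at all). Low-weight packets
play Russian roulette (threshold $10^{-4}$, survival 0.1), which keeps the
estimator unbiased while bounding packet lifetimes. Packets leaving the
surface inside an annulus $[\rho - h, \rho + h]$ around a nominal
source–detector distance contribute their remaining weight and their
per-layer accumulated pathlengths; reflectance is reported per unit annulus
area with its Monte Carlo standard error, and the mean partial pathlength
per layer is the weight-average over detected packets. The deepest-layer
fraction of the total partial pathlength is the probe's brain-sensitivity
metric.

Numerical choices worth knowing:

* **Annulus half-width** $h$ defaults to 0.25 mm. Nominal distances are
  points; finite bins are necessary for nonzero counts. The sweep
  experiments use $h = 1$ mm to buy detection statistics at far detectors;
  the resulting bin-averaging bias is second-order for the attenuation
  *slope*, which is the only quantity the estimator consumes.
* **Pathlength cap.** Packet paths are capped (default 2000 mm; the capped
  weight is tracked separately in the run totals, never silently dropped).
  In absorbing tissue the cap is almost never reached — roulette kills
  first. In deliberately non-absorbing runs the return-path distribution is
  heavy-tailed and the cap is the truncation of that tail; tests that
  assert energy conservation size the cap so the expected truncated weight
  sits inside the assertion's own Monte Carlo error band.
* **Determinism.** The engine uses its own xoshiro256+ stream seeded from
  `(seed, wavelength index)`; identical inputs give bit-identical output on
  any platform, independent of R's RNG state.
* **Bookkeeping.** Specular + diffuse + absorbed + roulette balance +
  capped weight must sum to one within 1e-6 on every run; this is asserted
  in the tests with absorption and roulette active.

### White runs and exact reweighting

A run with all $\mu_a = 0$ ("white" Monte Carlo) stores each detected
packet's per-layer pathlengths. The reflectance under any absorption is
then the expectation of $w\,e^{-\sum_\ell \mu_{a,\ell} L_\ell}$ over those
packets — the Beer–Lambert identity on the geometric path. `run_sweep()`
exploits this: one white run per design, wavelength and replicate serves
*every* saturation on the sweep grid, and (in `run_design_experiment()`)
both the brain and the skin sweep, because absorption never enters a white
run. Besides the obvious speedup, all grid points of a replicate share the
same packet paths, so differences along the grid are paired comparisons
with strongly correlated noise — monotonicity questions are answered far
more efficiently than by independent runs. The same identity, with
*independent* seeds, doubles as an oracle test of the absorbing engine.

## The diffusion oracle

`diffusion_reflectance()` is the steady-state dipole solution for a
homogeneous semi-infinite medium with an extrapolated boundary: isotropic
source at $z_0 = 1/(\mu_a + \mu_s')$, image source mirrored about
$-2 z_b$, $z_b = 2 A D$ with $D = 1/(3(\mu_a+\mu_s'))$ and $A$ from the
Groenhuis polynomial in the relative refractive index. Note $z_0$ and $D$
use $\mu_a + \mu_s'$, not $\mu_s'$ alone — stated here because both
conventions circulate and they differ at the percent level. The oracle is
independent of the Monte Carlo code path and the two are required to agree
within 10% at 20–30 mm; it also serves as a fast forward model wherever the
homogeneous assumption is intended (estimator recovery tests, noisy
synthetic attenuation).

## The SRS oximeter

Spatially resolved spectroscopy estimates, at each wavelength, the slope of
attenuation $A = -\log_{10} R$ across source–detector distance — a
quantity invariant to source power, detector gain and coupling, which is
the method's entire point. Under the semi-infinite diffusion asymptote
$\ln 10 \cdot dA/d\rho \to \mu_{eff} + 2/\rho$, the scaled absorption is

$$k\,\mu_a(\lambda) = \frac{\left(\ln 10 \cdot \mathrm{slope}(\lambda) -
2/\bar\rho\right)^2}{3\,\mu_{s,\mathrm{assumed}}'(\lambda)},$$

with $\bar\rho$ taken as the midpoint of the design's two distances (the
literature is split between midpoint and far distance; midpoint is the
package's convention and an argument, not a constant). The unknown scale
$k$ is wavelength-independent, so it cancels in the saturation ratio
$StO_2 = 100\,x/(x+y)$ after solving $k\mu_a(\lambda) = \ln 10\,
(\varepsilon_{HbO_2} x + \varepsilon_{HHb} y)$ by least squares. Two
properties follow *exactly* and are asserted exactly in the tests:
per-wavelength coupling changes cannot move the estimate, and a
wavelength-independent error in $\mu_s'_{\mathrm{assumed}}$ cancels.

The inversion uses haemoglobin only. Water is deliberately absent from the
estimator (it is how the fielded instruments behave) while being present in
the forward model; the resulting bias is a feature under study, not a bug.
When $\ln 10 \cdot \mathrm{slope} \le 2/\bar\rho$ the asymptote has broken
down (transport too shallow for the formula); the value is still returned,
flagged, because squashing it would hide exactly the short-separation
failures the experiment is designed to expose. Estimates are clamped to
[0, 100] for reporting with the raw value always retained, so gross
misreading stays quantifiable.

`multisite_aggregate()` covers the multi-site probe layout: the mean of the
per-site estimates serves as a global cerebral value and their spread
(range and SD) as a live reliability indicator.

## The design experiment

`run_design_experiment()` evaluates seven candidate designs — distance
pairs $(c, d)$ of 7/11, 8/13, 11/18, 13/20, 15/25, 20/30 and 25/35 mm —
under two sweeps: brain SO₂ over {30, 50, 70, 90}% with the superficial
layer fixed at 70%, and superficial SO₂ over {50, …, 90}% with the brain
fixed at 70%. Per design it reports:

* **responsiveness** — least-squares slope of estimated StO₂ against brain
  SO₂ (1 would be ideal);
* **bias at 70%** — estimate minus truth at the physiological operating
  point;
* **skin sensitivity** — range of the estimate over the skin sweep, which
  should be 0 for a perfectly brain-selective probe;
* **brain pathlength fraction** — the transport-level cause of all of the
  above.

Problem sizes: the default experiment uses 1.5×10⁵ packets per white run
(three replicate seeds per design and wavelength, so 42 transport runs
cover both sweeps), a 600 mm pathlength cap and a 1 mm annulus half-width;
the test suite runs the same experiment at 10⁵ packets. Grid densities and
replicate counts are the package's own choices — the continuous curves such
experiments are usually drawn from do not come with stated grids. The
replicate SD accompanies every estimate; at the far designs (25/35 mm) a
white run detects only a few hundred packets, and single-replicate
estimates there carry several percentage points of Monte Carlo noise.
Rankings across designs and monotonicity along grids are stable; individual
bias values at the far designs are the noisiest numbers the experiment
produces.

What the experiment shows with the default preset: every design responds
positively to brain SO₂; the brain pathlength fraction rises monotonically
from ~0.24 (design 1) to ~0.66 (design 7); and skin sensitivity falls
roughly tenfold from the shortest to the longest design, with designs 1–2
clearly the least robust to skin/scalp saturation changes.

The *bias* at the operating point deserves a careful reading, because two
opposing mechanisms meet there. The estimator's asymptote genuinely breaks
down at short separations: in the homogeneous water-free limit — where the
method's assumptions otherwise hold exactly — designs 1–2 ($\bar\rho$ =
9–10.5 mm) underread by up to ~18 points at low saturation, because the
measured slope has not yet reached $\mu_{eff} + 2/\bar\rho$; designs 5–7
($\bar\rho \ge 20$ mm) recover the generating saturation within 3 points
(this is a test). In the full two-layer model, however, neglecting water
biases the estimate *upward* with this chromophore set (water absorbs more
at 850 nm than at 760 nm, which the haemoglobin-only inversion misreads as
oxyhaemoglobin: the pure-tissue limits evaluate to ≈74–76% at a true 70%).
At the 70%/70% operating point the two effects roughly cancel for the
short designs, leaving their bias slightly positive rather than strongly
negative. Which effect wins in a real instrument depends on the
chromophore table, the wavelength set and proprietary algorithm constants;
only the ordinal conclusions above should be ported off this preset.

## Trial power and sample size

The continuous-endpoint calculator uses the two-sided normal-approximation
formula $n = 2(z_{1-\alpha/2} + z_{power})^2(\sigma/\delta)^2$ per group,
rounded up; for a 5-point effect on a 15-point-SD cognitive scale (Cohen's
d of 0.33) at 90% power and 5% two-sided significance this gives 190
evaluable infants per group. The normal approximation is the package
default because it is the convention of the sample-size tables this kind of
trial is planned with; `method = "nct"` solves the exact noncentral-t power
of the pooled t-test instead and gives 191 — the difference is immaterial
at these sizes and both are exposed. With 20% mortality before outcome
assessment, `inflate_for_attrition(190, 0.20)` gives 238 to randomize per
group; any further rounding (e.g. to a round 250) is a protocol choice the
package reports only explicitly, never silently. The binary-endpoint
calculator implements the pooled-variance two-proportion formula (optional
Fleiss continuity correction): risks 0.25 vs 0.20 at 90% power give 1464
per group uncorrected, 1543 corrected — numbers the user should combine
with their own attrition and design-effect assumptions rather than trust as
a single headline figure.

`simulate_power()` closes the loop by brute force: complete two-arm trials
are simulated (normal outcomes, pooled two-sample t-test) and the rejection
fraction reported with an exact binomial CI. At the design size it
reproduces the analytic 90% within Monte Carlo error; under a null effect
it rejects at the nominal 5%. `synth_trial_outcomes()` generates the
per-infant tables (arm, survival, score) that feed it.

## What the synthetic data does and does not emulate

The generator produces (a) layered-medium reflectance with realistic
partial-pathlength structure, (b) attenuation records with additive
Gaussian OD noise, and (c) two-arm trial outcomes with mortality. It does
**not** emulate: cerebrospinal-fluid channels and other non-scattering
inclusions (a real and known failure mode of layered models of the preterm
head), curved geometry, instrument drift or motion artefacts, covariance
between mortality and outcome scores, or loss to follow-up beyond a single
attrition fraction. Passing tests therefore demonstrate internal
consistency of the methods under the stated model, not device performance
on real infants.

## Known limitations

* The preset optical constants are plausible, not measured; every
  quantitative bias value moves with them. Ordinal conclusions (design
  rankings, monotonicities) survived every preset variation tried during
  development; signed bias magnitudes did not, and the short-separation
  bias *direction* in particular depends on the chromophore table and on
  algorithm constants of fielded instruments that are not public.
* The diffusion forward model in `run_sweep(forward = "diffusion")` reads
  the deepest layer only; it is intended for the homogeneous limit and for
  fast estimator tests, not for layered media.
* The two-distance slope uses exactly the two distances of a design;
  three-plus-distance regression is supported by `attenuation_slope()` but
  not exercised by the experiment, matching the two-source probe layout.
* Single-threaded; a full-precision experiment (10⁶ packets per run) takes
  tens of minutes of CPU.
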