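---
title: "Splitting total concentrations into nanoparticle and dissolved forms: model and methods"
author: "npsplit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting total concentrations into nanoparticle and dissolved forms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npsplit)
```

## The scientific problem

Polymeric nanoparticle products that co-encapsulate irinotecan and SN-38
are dosed intravenously, and routine bioanalytics measure only *total*
plasma concentrations: particle-bound (NP) plus dissolved (S) drug. The
two forms have opposite clinical meaning — the NP form is the tumour-
targeted depot, the S form the systemically active (and toxic) species —
so a dose-exposure argument built on totals alone is uninterpretable.

`npsplit` implements the deconvolution strategy used in population
pharmacokinetics: fix what is already known (the disposition of dissolved
irinotecan, characterised for decades), encode how the formulation
constrains the dose (the NP/S split of each drug in the vial), and let a
mixed-effects model attribute the remaining signal in total irinotecan,
total SN-38 and SN-38G to the NP forms and their release rates.

## Structural model

Eleven compartments, all processes first order, amounts in mg, volumes in
L, time in h, concentrations reported in ng/mL (mg/L × 1000):

| block | compartments | parameters |
|---|---|---|
| NP-irinotecan | central (1), peripheral (2) | `V1`, `V2`, `Q1`, release `K13` |
| S-irinotecan | central (3), rapid (4), slow (5) | `V3`-`V5`, `Q2`, `Q3`, `CL1` (literature, fixed) |
| NP-SN-38 | central (6), peripheral (7) | shares `V1`, `V2`, `Q1`; release `K68` |
| S-SN-38 | central (8), peripheral (9) | `V8`, `V9`, `Q5`, `CL2` (to SN-38G) |
| SN-38G | central (10), peripheral (11) | `V10`, `V9` (shared), `Q6`, `CL3` |

Key structural commitments, each of which is what makes the total
concentration data informative about the split:

* release into the dissolved central compartment is the **only**
  elimination route of each NP form;
* the NP disposition parameters are shared between the two drugs, because
  both ride in the same particle;
* a fixed 3% of irinotecan clearance is conversion to SN-38. We implement
  the 3% on a **molar** basis (mass flux scaled by the molar-mass ratio
  392.40/586.68). The alternative mass-basis reading changes the predicted
  dissolved-SN-38 exposure by about 1.6% and is inconsistent with the
  published exposure table, which the molar reading reproduces within
  printed rounding;
* S-SN-38 is eliminated exclusively by glucuronidation; the SN-38 to
  SN-38G transfer is modelled 1:1 in mass. The stoichiometric factor is
  unidentifiable — any molar correction would be absorbed by the estimated
  `CL3`/`V10` — so the convention is documented rather than estimated;
* observation model: total irinotecan = NP + S irinotecan concentration,
  total SN-38 = NP + S SN-38 concentration, SN-38G is dissolved only.

Two dosing constants are not stated with the published model and are fixed
here by internal consistency with its exposure table: the infusion
duration (1.5 h — the value at which the closed-form end-of-infusion
concentrations of both NP forms reproduce the table's Cmax entries) and
the body surface area of the typical subject (1.6 m², from the exact
identity AUC(S-iri) = BSA × dose-per-m² / CL1). Both are arguments of
`dose_regimen()`, not hidden constants.

## Exact simulation

With first-order kinetics the system is `dA/dt = M A + u(t)` with
piecewise-constant `u`. `K13 = 64.4/h` sits four orders of magnitude above
the slowest terminal phases, so the system is stiff and is solved
*exactly*: eigendecomposition of `M` gives the matrix exponential during
and after the infusion (`expm1` guards the small-eigenvalue limit). For
degenerate parameter sets with a defective eigensystem (for example
`Q1 = K13 = 0`, used in tests) the solver falls back to stepwise
`Matrix::expm()` on the forcing-augmented matrix. Agreement with an
implicit stiff integrator (`deSolve::lsoda` at `rtol = 1e-11`) is asserted
at `1e-6` relative in the test suite.

AUCs are not quadrature: integrating the linear system gives
`∫ A dt = M⁻¹ (A(T) − U(T))` exactly, and `AUC(0,∞) = −M⁻¹ U_total`. The
test suite checks these against the hand-derived closed forms
(`AUC(S-iri) = D/CL1`, `AUC(NP-SN-38) = 0.98 D /(K68 V1)`, ...) at 0.1%.
Cmax is taken on an evaluation grid: 0.025 h spacing around the infusion
(the NP forms peak exactly at end of infusion, which is always included as
a grid point), 0.05 h to 48 h (the dissolved-SN-38 peak falls shortly
after the infusion), 0.5 h beyond.

## Population model and the synthetic Phase-I trial

Between-subject variability is log-normal and independent across
parameters (`theta_i = theta exp(eta_i)`, `eta ~ N(0, omega²)`); the
shared NP parameters receive a single eta by construction. Residual error
is proportional with a separate sigma per analyte (0.21, 0.416, 0.308 for
irinotecan, SN-38, SN-38G). "BSV%" is interpreted as `100 × sd(log)`, the
standard pharmacometric reporting, not back-transformed through
`sqrt(log(1+CV²))`.

Because the clinical dataset is not public, `default_design()` +
`simulate_trial()` generate trials with the statistical structure the
analysis assumes: 7 cohorts of 1/1/1/5/7/3/3 subjects (21 total), SN-38
doses 5–50 mg/m² at the fixed 1:1.6 SN-38:irinotecan per-m² ratio
(≈1:1 molar), 17 samples per subject from pre-dose to 169.5 h, all three
analytes observed at every time. Demographics are carried as metadata only
(the final model retained no covariates); every subject uses BSA 1.6 m²
(reported weights are nearly constant and no heights are available to do
better). The pre-dose sample is emitted as a non-evaluable record
(`MDV = 1`, `DV = 0`).

What the generator deliberately does **not** emulate: assay quantification
limits and censoring, dropout and missed samples, occasion-to-occasion
variability, eta correlations, and any covariate structure. Passing tests
therefore demonstrate internal consistency of estimation and prediction
under the stated statistical assumptions — not robustness to the
real-data pathologies a clinical analysis would face.

Residual draws that would produce negative concentrations are floored at
zero and flagged. Such zero observations are excluded from the likelihood
(like pre-dose records): under a proportional error model the density of a
zero observation is unbounded as the prediction vanishes, so keeping them
would make the likelihood improper.

## Estimation: Laplace marginal likelihood

The objective is the full `−2 log` marginal likelihood (all `2π` constants
included). Per subject, the integral over eta is approximated by Laplace's
method at the posterior mode: `h(η̂) − k log 2π + log det(H/2)` with
`h = −2 log p(y|η)p(η)` and `H = ∇²h(η̂)`. The observation density is
`Normal(f, (σ f)²)` at the *individual* prediction `f` — the conventional
pairing for Laplace. A 64-point Gauss–Hermite oracle in the test suite
confirms the implementation: agreement to `6e-5` at `omega = 0.05` (where
the integrand is near-Gaussian) and graceful degradation (≈0.013) at
`omega = 0.3`, the expected second-order behaviour.

Numerical choices, in decreasing order of importance:

* **Inner problem.** The mode search uses an analytic gradient assembled
  from a finite-difference Jacobian of the predictions (step `1e-4` on
  eta; central by default, forward via `control$fd` when speed matters).
  Two interchangeable curvature treatments are provided
  (`control$inner_hessian`): `"fd"` differentiates the gradient once more
  and optimises by BFGS with a Newton polish — the exact second-order
  Laplace, used by `np_neg2ll()` and validated against Gauss–Hermite
  quadrature; `"gn"` assembles the Gauss–Newton curvature from the same
  Jacobian that gives the gradient (dropping the
  second-derivative-of-prediction terms), drives a damped Newton
  iteration with it (BFGS takes over on the rare stalls far from a
  basin), and uses it in the Laplace determinant. The Gauss–Newton form
  is several-fold cheaper and varies smoothly with the fixed effects,
  which matters for the outer search. With omegas near 1 (`V2` 94.5%,
  `CL3` 115.9%, `V10` 122.1%) the penalised deviance is genuinely
  multimodal; on a cold start the solver therefore probes a deterministic
  set of omega-scaled starting points (subject-keyed congruential draws,
  independent of the R RNG stream) and keeps the best mode. Within an
  outer optimisation the modes are warm-started from the previous
  iteration, and one cold pass before the optimisation starts makes all
  evaluations the optimiser sees mutually consistent.
* **Outer problem.** Free thetas/omegas/sigmas are optimised as
  log-offsets from their starting values (positivity by construction and
  a well-scaled search space). Two methods: Nelder–Mead with
  collapse-restarts (default; Brent for a single free parameter), and a
  deterministic cyclic parabolic coordinate search
  (`control$outer_method = "cyclic"`) that probes each coordinate on a
  shrinking bracket, expands while the minimum sits on the bracket edge,
  and refines by parabolic interpolation. The cyclic search makes its
  decisions from OFV differences across wide brackets, which keeps it
  robust to the `~0.05`-level history dependence of warm-started inner
  modes; it is the method used in the parameter-recovery experiment.
* **Random-effects set.** By default the likelihood integrates etas over
  the seven parameters whose BSV the final model *estimated* (`CL1`, `V1`,
  `V2`, `K68`, `CL2`, `CL3`, `V10`); the literature-fixed BSVs of the
  S-irinotecan block can be added via `eta_on`. On trials simulated with
  the full 12-eta truth, fits with the 9-eta set (adding `Q2`, `Q3`) and
  the full 12-eta set give estimates agreeing to three digits, while a
  3-eta restriction is badly misspecified — the large omitted omegas
  corrupt the objective. The parameter-recovery experiment in the test
  suite uses the 9-eta set.
* The literature parameters (`V3`, `V4`, `V5`, `Q2`, `Q3` and their BSVs)
  are never estimated — freeing them triggers a warning — because holding
  them is precisely what identifies the NP/S split from total data.

`FitResult` diagnostics follow the field's conventions: gradient norm at
the optimum, condition number of the (numerical) information matrix, eta
shrinkage `1 − sd(η̂)/ω`, and the `ΔOFV ≥ 3.84` likelihood-ratio gate
(`ofv_test()`) for one extra parameter.

## Model evaluation

`np_vpc()` simulates `n_rep` replicate trials of a design and summarises
simulated observations per cohort, analyte and nominal time as the median
and the 90% prediction interval (5th/95th percentiles, type-7
linear-interpolation quantiles). Simulated and nominal times coincide, so
no binning is applied; single-subject cohorts still get bands. A
bootstrap is deliberately not provided: resampling 21 subjects cannot
probe whether literature-anchored parameters are robust, which is the
relevant question for this model.

## Problem sizes used in the automated checks

The test suite runs the deterministic oracles at full precision and keeps
the stochastic experiments at deliberately chosen sizes: parameter
recovery uses 20 replicate trials of the full 21-subject design with
`{K68, CL2, V1}` free (forward-difference Jacobians, outer tolerance
`3e-5`, outer iteration cap 150 — estimates are needed to a few percent,
far inside the ±20% acceptance band), and the VPC self-coverage check uses
500 replicates. Monte-Carlo sampler checks use 10,000 draws.

## Known limitations

* Linear kinetics only: no saturable release, no enterohepatic
  recirculation, no lactone/carboxylate interconversion.
* The NP/S split of the *dose* is fixed at the storage-equilibrium values
  (0.15/0.98); in-vial variability is not modelled.
* Laplace (not adaptive quadrature) estimation; with omegas above ~1 the
  marginal likelihood approximation error is visible (order 1e-2 per
  subject) though far below the resolution of any likelihood-ratio
  decision at the 3.84 threshold.
* Single-dose only; multi-cycle accumulation is out of scope.
* The dissolved-SN-38 elimination half-life implied by the parameter set
  (ln 2 · V8/CL2 ≈ 0.17 h central; ≈4.9 h terminal) brackets but does not
  reproduce every derived quantity quoted alongside the published model;
  such derived values are not used as checks here.
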