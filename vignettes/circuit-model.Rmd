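---
title: "The frontostriatal circuit model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The frontostriatal circuit model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frontostriatal)
```

## The scientific problem

Schizophrenia presents an apparent paradox: reduced prefrontal cortex (PFC)
activity ("hypofrontality") coexists with *elevated* striatal dopamine.
This package implements a minimal circuit explanation. The PFC sends
glutamatergic projections to striatal medium spiny neurons; the striatum
sends GABAergic projections to the midbrain DA nuclei (substantia nigra /
ventral tegmental area); and the DA nuclei release dopamine back into the
striatum. Lower PFC drive means less striatal activity, less inhibition of
the DA nuclei, and hence more DA release — an inverse PFC–dopamine
relationship closed by two presynaptic D2 receptor populations:

* **heteroreceptors** on the frontostriatal glutamatergic terminals
  (coefficient `b`), which depress corticostriatal transmission by a factor
  `1 − bP`, and
* **autoreceptors** on the dopaminergic terminals (coefficient `a`), which
  suppress release by `1 − aP`,

where `P = Y/(1+Y)` is the D2 occupancy by dopamine and `Y = [DA]/K_DA` the
DA concentration normalized by its dissociation constant.

## Model and assumptions

### Dynamics and equilibrium

The full dynamics (`dynamics_rhs()`, `simulate_circuit()`) relax each
population with its own time constant, with activation function
`f(x) = tanh(x)` or its linearization `f(x) = x`:

$$\tau_s \dot x_s = -x_s + W_{ps} f(x_p)(1 - bP), \qquad
  \tau_d \dot x_d = -x_d + J_d - W_{sd} f(x_s), \qquad
  \tau_y \dot y = -y + W_{dy} x_d (1 - aP).$$

All quantitative results come from the *linearized equilibrium* in
normalized variables (connectivity products absorbed into the state, so the
`W` coefficients default to 1):

$$X_s = X_p (1 - bP), \quad X_d = J_d - X_s, \quad Y = X_d (1 - aP),
  \quad P = \frac{Y}{1+Y},$$

subject to the physiological constraint that all states are positive. The
tanh nonlinearity is retained only for time-domain simulation; every
reported number derives from the linear system, whose fixed point is what
`solve_equilibrium()` returns.

Assumptions worth keeping in mind: populations are homogeneous rate units;
a single dissociation constant `K_DA` serves all D2 receptor pools
(presynaptic hetero- and autoreceptors alike); receptor density does not
change on the timescale of acute depletion; and only the low-affinity
single-site description of D2 binding is modelled — high-affinity receptor
states, D1 receptors, and tracer kinetics are out of scope.

### Key parameters

| parameter | meaning | units | default |
|---|---|---|---|
| `a` | D2 autoreceptor suppression of DA release | dimensionless | 0 (0.2 in the "both receptors" analyses) |
| `b` | D2 heteroreceptor depression of corticostriatal input | dimensionless | 0–1 sweeps |
| `j_d` | tonic drive to the DA nuclei | dimensionless | 1 (pure convention: it sets the scale of `Y`) |
| `alpha` | residual DA fraction after acute depletion | fraction | 0.3 (70% depletion) |
| `b_max` | relative D2 receptor density | HC = 1 | patients 1.2 |
| `tau_s, tau_d, tau_y` | relaxation time constants | arbitrary time | 1 |

## Numerical choices

* **Equilibrium solver.** The fixed point is a scalar root in `Y`. We use
  damped fixed-point iteration (damping 0.5, tolerance 1e-10, at most
  10,000 iterations), a bracketed `uniroot()` scan over `(0, W_dy J_d]` as
  fallback, and a final Newton polish that drives the residual to machine
  precision (needed so the closed-form identity `Y² = 1 − X_p` at
  `(a, b) = (0, 1)` holds to 1e-10). On the physical branch the positive
  solution is unique; solutions violating positivity raise an infeasibility
  error rather than returning a nonphysical state.
* **Gain clamping.** The modulation factors `1 − aP` and `1 − bP` are
  clamped at zero: negative transmission is unphysical, and the analyses
  never operate near `aP = 1` or `bP = 1`.
* **Integration.** `simulate_circuit()` uses fixed-step 4th-order
  Runge–Kutta (`deSolve::ode`, method `"rk4"`) with `dt = min(τ)/20` by
  default and a divergence guard. For stable linear parameterizations the
  terminal state matches the algebraic equilibrium to better than 1e-6,
  which the test suite checks.
* **Sweeps.** Infeasible grid points are flagged (`feasible = FALSE`) and
  carried as `NA`, never silently dropped.
* **Rounding.** Occupancies are formatted to one decimal percent and
  normalized DA levels to three decimals at the reporting layer only;
  internally everything is carried at full precision as fractions. Two
  published reference numbers (the Model 1 drug occupancy of 52.3% and the
  67% release elevation with both receptors) are reproducible only by
  rounding an intermediate (the dose 1.39, the release values 0.50/0.30)
  before the final division; the package computes exactly (52.4%, 65.7%)
  and the tests document the distinction rather than imitating the
  intermediate rounding.

## Calibration from depletion imaging

Acute DA depletion (AMPT) unmasks D2 receptors, so the binding-potential
ratio `(1+Y)/(1+αY)` estimates the baseline occupancy. Two canonical
calibrations are built by `canonical_models()` from the packaged table of
published occupancies:

* **Model 1** uses the single study reporting both cohorts: 12% (HC) and
  21% (SZ), with relative patient density 1.2.
* **Model 2** averages the five control studies (23.6%), extrapolates the
  patient value with Model 1's 21/12 ratio (41.3%), and rounds both to
  whole percent (24%, 41%) — the rounding is part of the calibration
  recipe, not a numerical accident.

Cross-cohort comparisons (`efficacy_and_pfc()`, `sz_hc_differences()`)
scale the D2 coefficients with each cohort's relative density
(`a_eff = a·B_max`): a patient with 1.2× the receptors feels 1.2× the
presynaptic modulation. Generic circuit sweeps use the raw coefficients
(`B_max = 1`). The efficacy difference `ΔV_ps = b(P_HC·1 − P_SZ·1.2)` does
not involve `a`, and the tests check it is bitwise identical across
autoreceptor values. Whether the density scaling should also apply inside
the depletion-to-PFC transformation is undefined at `(a, b) ≠ (0, 0)`; both
options are exposed through `scale_with_density` (moot at the default
`(0, 0)`, where the transformation reduces to `X_p = J_d − Y`).

## Synthetic data: what it emulates and what it does not

`generate_depletion_study()` emulates a per-subject depletion-imaging
experiment: baseline `BP ∝ B_max/(1+Y)`, depleted `BP ∝ B_max/(1+αY)`,
each multiplied by independent lognormal noise of a chosen coefficient of
variation — multiplicative because BP is positive and imaging noise scales
with signal. It does *not* emulate between-subject variability in the true
DA level, scanner or tracer differences between studies, partial-volume
effects, or incomplete/variable depletion; parameter-recovery results
therefore show that the estimator inverts its own generative model, not
that real imaging data are this well behaved. Noisy observations can show
a BP decrease; the per-subject estimator censors these at `Y = 0`, the
boundary of the physical domain.

`generate_outcome_records()` draws symptom-change records on (or around) a
chosen line relating the PANSS positive-subscale change to model-derived
PFC activity. The published per-patient depletion responses exist only as
a figure in the original imaging study, so the regression machinery is
validated by recovery on synthetic data: exact recovery (R² = 1, machine
precision) on noise-free records, and slope recovery within the fitted 95%
interval on seeded noisy records at the study's sample size (n = 14,
residual SD a few score points). The reference sample size and default
`beta` range \[0.02, 0.45\] span the feasible depletion-response domain at
`α = 0.3`.

## Problem sizes

Everything here is closed-form or a scalar fixed point: equilibrium sweeps
use a few hundred grid points, oracle comparisons 100 random parameter
draws, trajectory checks integrate four ODEs for ~100 time units, and
Monte-Carlo recovery uses 50–200 synthetic subjects. The full test suite
and the acceptance script each run in seconds.

## Known limitations

* The equilibrium analysis is linear; the tanh model is only verified to
  relax to nearby fixed points, not analyzed for bifurcations.
* The calibration takes the published occupancies at face value: no
  meta-analytic weighting, no uncertainty propagation onto Model 1/2
  parameters.
* The net-binding criterion is an occupancy-level construct; it says
  nothing about pharmacokinetics of specific drugs or side-effect
  thresholds.
* Extrastriatal D2 receptors, high-affinity receptor states, and D1
  pharmacology are outside the model.
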