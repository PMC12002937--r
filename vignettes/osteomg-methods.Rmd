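---
title: "Coupled kinetics of Mg implant corrosion and peri-implant bone mineralization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{osteomg methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteomg)
```

# The scientific problem

Biodegradable magnesium–gadolinium (Mg-xGd) implants corrode in vivo,
releasing Mg²⁺ ions into the peri-implant tissue while new bone forms
around them. `osteomg` models three coupled processes as one ODE system:

1. **Implant degradation** — the fraction of implant volume lost over
   time, `Vloss(t)`.
2. **Bone remodelling** — the maturation of collagen matrix, the decay of
   mineralization inhibitors, the fate of crystal nucleation sites, and
   the resulting mineral content `H`, identified with the relative bone
   volume fraction BV/TV.
3. **Hydroxyapatite ultrastructure** — the growth of crystal platelet
   width and the contraction/recovery of the lattice spacing as Mg²⁺
   substitutes Ca²⁺ and is later cleared again.

The package also contains everything needed to *use* such a model when
the experimental data are sparse summaries: a staged multi-start CMA-ES
calibration, residual-based error metrics, variance-based global
sensitivity analysis, and a synthetic-study generator for parameter
recovery experiments.

# Model equations

## Degradation

Two laws for the volume-loss rate are implemented
(`degradationParams()`), both with closed-form antiderivatives used
throughout as oracles and in fast loss evaluations:

* **Diffusion-limited power law**: `dVloss/dt = m1 / sqrt(t + eps)`,
  hence `Vloss(t) = 2 m1 (sqrt(t+eps) − sqrt(eps))`. The tiny offset
  `eps = 1e-30` regularizes the `t = 0` singularity. The exponent is a
  rendering-level ambiguity of the source model; the diffusion-limited
  value `−1/2` is the default because the law is explicitly
  diffusion-based, the `eps` workaround only makes sense for a
  singularity at zero, and other exponents produce implausible
  magnitudes with the calibrated `m1 ≈ 0.015`. The exponent is exposed
  as a parameter for users who want a different kinetic order.
* **Surface-rate law with precipitation**:
  `dVloss/dt = r′ d′ / (r′ t + d′)`, hence
  `Vloss(t) = d′ log(1 + r′ t / d′)`. `r′` (1/day) is the corrosion
  rate and `d′` the precipitated-material fraction, both pre-scaled by
  the implant's initial surface-to-volume ratio.

Volume loss is carried internally as a fraction; percent appears only at
the I/O boundary. Time is in **days** throughout — the finer of the two
units in which such studies report — and rate constants are per day.

## Remodelling

With naive matrix `x1(0) = 1`, mature matrix `x2(0) = 0`, inhibitor
`I(0) = 1`, nucleators `N(0) = 0`, mineral `H(0) = H0`:

```
x1' = −k1 x1
x2' = +k1 x1
I'  = v1 x1 − r1 x2 I + m2 dVloss/dt
N'  = k2 k1 x1 − r2 H' N
H'  = k3 · b/(b + I^a) · N
```

The Hill gate `b/(b + I^a)` (defaults `a = 10`, `b = 0.001`) keeps
mineralization off until the inhibitor pool has decayed to order
`b^(1/a) ≈ 0.5`; `k2 = 1` assumes one nucleation site per maturation
event. `H'` is computed first and substituted into `N'`, so no algebraic
loop exists.

**Choice of the inhibitor removal term.** Two readings of "inhibitors
are removed during matrix maturation" are implemented. Tying removal to
the maturation *events* (`−r1 (k1 x1) I`) shuts the removal pathway once
`x1` has decayed (days); any later Mg²⁺ influx then accumulates
indefinitely and mineral never forms around a degrading implant — the
model cannot produce the delayed-but-substantial bone growth that is its
point. Tying removal to the amount of mature matrix *present*
(`−r1 x2 I`) keeps a sink active for as long as matrix exists, so the
Mg-driven inhibitor spike decays and mineralization resumes with a
material-dependent delay. The second form is therefore the default
(`inhibitor_removal = "mature_matrix"`); the event form remains
available as `"maturation_rate"` for comparison, and a unit test pins
down the qualitative difference between the two.

With the calibrated parameter values this default reproduces the
expected ordering: mineralization sets on after ~3 days for Ti, ~12 days
for Mg-5Gd and ~15 days for Mg-10Gd — later for the slower-corroding
alloy, whose sustained ion release keeps the inhibitor elevated longer.

## Ultrastructure

```
Cw' = k4 · Cw · (H')^k6
L'  = −k7 · dVloss/dt · (L − Lmin) + k8 · (Lmax − L)
```

`Cw` is the crystal width normalized by 15 nm; `k6 ≥ 1` is the order of
the precipitation process; `k4` absorbs the crystallization constant,
the surface-area proportionality and the supersaturation scale. The
lattice spacing `L` (Å, per crystallographic plane, defaults
(002): 3.403–3.447 Å, (310): 2.243–2.281 Å) contracts toward `Lmin`
while ions substitute at a rate proportional to the corrosion rate and
relaxes back toward `Lmax` at the clearance rate `k8`.

Both equations have closed-form solutions used as independent oracles:
the width equation is separable
(`Cw(t) = C0 exp(k4 ∫ (H')^k6 ds)`), the lattice equation is linear
first-order, solved with an integrating factor whose exponent
`k7 Vloss(t) + k8 t` uses the analytic cumulative loss (the quadrature
integrand `exp(A(s) − A(t))` is bounded by 1, so the solution is
overflow-safe by construction and provably stays inside
`[Lmin, Lmax]`).

**The width seed `C0`.** A literal zero initial width makes the
multiplicative growth law identically zero, yet fitted width curves are
nonzero — an implicit seed is required. The default is `C0 = 1e-3`
(normalized units). `C0` is exactly confounded with the overall scale of
the fitted curve (`Cw` is linear in `C0`; a unit test asserts this
exactly), so it is held fixed during calibration rather than fitted.

# Numerical implementation

* The eight states (5 remodelling + volume loss + 2 ultrastructure) are
  integrated **jointly in one solver call** (`simulateModel()`), so the
  mineralization rate seen by the width equation is exactly the one the
  remodelling block produces. The degradation rate always enters as its
  analytic function of time, never as a numerical derivative.
* The right-hand side is compiled C (deSolve's compiled-model
  interface); `lsoda` with `rtol = 1e-8`, `atol = 1e-10` by default.
* Fractional powers `(H')^k6` require a nonnegative base; tiny negative
  values from floating-point noise are clipped to zero inside the RHS.
  After solving, states that dip within `1e-8` of zero are floored at
  zero and `H` is made exactly non-decreasing when its numerical dips
  are within that same noise floor; larger violations are left visible.
* Closed-form evaluations integrate with adaptive Gauss–Kronrod
  quadrature (tolerance `1e-10`), which tolerates the kinks of
  interpolated rate functions.
* A solver that returns an incomplete or non-finite trajectory raises an
  error; during optimization such candidates are silently assigned a
  large penalty value.

# Calibration

The loss is the scalarized sum of per-variable mean squared residuals
(`1/n` weighting per variable) — a weighted sum, not a Pareto method.
For the Ti calibration two ridge penalties (`0.001 k3²`, `0.01 v1²`)
prevent unrealistically large rates, and an **artificial early BV/TV
point** at `t = 3` days with value `H(0)` anchors the lag phase, which
the sparse 4–32-week grid otherwise leaves unconstrained; its value
tracks `H(0)` when the initial mineral content is varied
(`h0ParameterStudy()`).

Optimization uses an in-package implementation of the standard
(μ/μ_w, λ) **CMA-ES** (rank-one + rank-μ covariance updates, cumulative
step-size adaptation), operating in a `[0,1]`-rescaled box with
clamp-plus-quadratic-penalty boundary handling. Starting points come
from **latin hypercube sampling** over the calibration bounds; every
start's seed derives deterministically from the master seed, so fits are
bit-reproducible. Defaults: initial step 0.25 box widths, default
population size, 500 generations, loss-change tolerance `1e-10`.

The **staged workflow** (`stagedWorkflow()`) mirrors the
material-transfer logic: (1) all bone/ultrastructure parameters are
fitted to Ti with `m2 = 0`, while degradation parameters are fitted per
Mg alloy on volume loss; (2) `k1, v1, r1, r2` are frozen and
`m2, k3, k4, k6` refitted on Mg-10Gd, with `k7, k8` fitted per plane on
the Mg-10Gd lattice data; (3) everything is fixed and applied to Mg-5Gd
as a pure prediction (optionally refitting the plane-specific ion
exchange rates, which are plausibly material-specific). Degradation
parameters are never re-optimized after stage 1.

With sparse noise-free data the Ti stage is only weakly identifiable:
several bone-parameter combinations reach near-identical loss, and the
ridge terms deliberately bias `k3` and `v1` downward, so recovered Ti
parameters should be read as one representative of a near-optimal set
rather than as unique estimates. The degradation parameters, by
contrast, are recovered to a fraction of a percent, and the stage-3
BV/TV prediction error stays far below the trajectory scale.

# Evaluation and sensitivity

`mae()` reports errors in data units; `nrmse()` divides RMSE by the
observed **range** (mean-normalization behind a flag) so values compare
across variables with different scales — the normalization convention is
a package choice. The 95% band is a constant half-width ribbon
`MOE = 1.96 σ/√n` around the trajectory, with `σ` the residual SD; 1.96
is the normal 97.5% quantile (the residual-based heuristic is reproduced
as such, not replaced by bootstrap or profile likelihood).

Sensitivity uses first-order (`Si`, Saltelli-2010 estimator) and
total-effect (`STi`, Jansen estimator) Sobol indices on a Saltelli
cross-sampling design of size `N(d+2)`. Inputs are uniform within ±20%
of the calibrated optimum (`makeRanges()`); for degradation parameters
the interval pools both alloys' optima (`pooledRanges()`). The design is
built on an in-package **Sobol' low-discrepancy sequence**
(Joe–Kuo direction numbers, validated point-for-point against an
independent reference implementation), with a Cranley–Patterson rotation
providing seeded replicates without losing the QMC convergence that
makes `N = 2^10` sufficient for screening; `N = 2^14` is recommended for
production runs. Parameters are flagged influential at `Si ≥ 0.05` or
`STi ≥ 0.1`.

Because the analysis needs a scalar output per model run, trajectories
are reduced — by default to the **mean over the experimental time grid**
(`modelOutputScalar()`); final-time value and L2 norm are alternatives.
The choice is deliberately exposed since no canonical reduction exists.

# The synthetic-study generator

`generateStudy()` is the statistical stand-in for the animal studies the
model was built for (whose numeric tables are not public): sparse
per-variable time grids (BV/TV and volume loss at 28–224 days, width and
(310) spacing at 4–12 weeks, (002) quantities at 10–32 weeks, or the
second design's 3–90-day BV/TV grid with `H(0) = 42.47`), six animals
per time point, per-animal **multiplicative** Gaussian noise with CV 10%
(measurement scatter in such studies scales with the value), except
lattice spacings, which get **additive** noise of 0.005 Å because their
dynamic range is a few hundredths of an Å. Truth parameters default to
the calibrated values; Mg-5Gd truth uses the Mg-10Gd bone parameters,
mirroring the transfer assumption. Out-of-bounds truth is rejected.

What passing recovery tests on these data shows — and what it does not:
the pipeline can identify the identifiable parameters from data of this
shape and noise level under the model that generated them. It says
nothing about structural misfit, non-Gaussian inter-animal variation,
or correlated measurement error in real studies.

# Mineralization lag

`computeLag()` uses the standard growth-curve construction: the tangent
at the point of maximum `dH/dt` is intersected with the baseline
`H = H(0)`. The exact `dH/dt` values written by the solver are used when
present. No operational lag definition is canonical for this model
class; the tangent construction is the package's choice and is validated
against the analytic lag of a logistic curve.

# Problem sizes and reproducibility

The shipped tests and the acceptance script run deliberately scaled-down
experiments chosen as the smallest sizes at which every conclusion is
stable: 3 LHS starts with ≤150–250 CMA-ES generations for the staged
recovery (10 starts × 500 generations are the production defaults),
Sobol screening at `N = 2^10`, and 200 property-sampled parameter sets
for the invariant checks. All randomness flows from explicit integer
seeds; dataset generation and sampling restore the caller's RNG state.

# Known limitations

* No spatial resolution: corrosion, ion transport and remodelling are
  homogeneous; no pH or electrochemistry.
* No explicit osteoblast/osteoclast populations and no mechanics.
* `H(0)`, the artificial-point convention and the ridge weights are
  study-design choices; the ridge weights in particular were set
  manually and may not transfer to other datasets.
* `C0` and the width scale are confounded; only relative width dynamics
  are meaningful.
* The crystal length is treated as fixed (observed not to change
  significantly); only width dynamics are modelled.
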