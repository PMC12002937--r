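# osteomg

Coupled kinetic modelling of biodegradable magnesium-implant corrosion,
peri-implant bone mineralization, and hydroxyapatite ultrastructure
change — with staged CMA-ES calibration, Sobol sensitivity analysis and
a synthetic-study generator for parameter-recovery experiments.

## Who this is for

Researchers modelling osseointegration around permanent (Ti) and
biodegradable (Mg-xGd) implants from sparse in-vivo summaries: median ±
SD time series of implant volume loss, relative bone volume fraction
(BV/TV), hydroxyapatite crystal width and (310)/(002) lattice spacing.

## The model

Implant degradation follows either a diffusion-limited power law or a
surface-rate law with precipitation shielding,

    dVloss/dt = m1 / √t        or        dVloss/dt = r′d′ / (r′t + d′),

both with closed-form cumulative loss. Bone formation extends a
Komarova-type mineralization system — naive collagen matrix x₁ maturing
at rate k₁, a generalized inhibitor I produced through the naive matrix
(v₁) and removed through the mature matrix (r₁), nucleators N created
with maturation and encapsulated by growing mineral (r₂) — with mineral
H ≡ BV/TV gated by a Hill function of the inhibitor:

    dH/dt = k₃ · b/(b + Iᵃ) · N,        dI/dt = v₁x₁ − r₁x₂I + m₂·dVloss/dt,

where the m₂ term couples Mg²⁺ release into the inhibitor pool (m₂ = 0
for Ti). The ultrastructure block adds crystal-width growth
dCw/dt = k₄·Cw·(dH/dt)^k₆ and lattice-spacing dynamics
dL/dt = −k₇·(dVloss/dt)·(L − Lmin) + k₈·(Lmax − L), describing Ca²⁺ → Mg²⁺
substitution and its later reversal. All eight states are integrated
jointly (compiled RHS, `lsoda`), and the width/lattice equations carry
closed-form solutions used as independent oracles in the tests.

## Worked example

Simulate an Mg-10Gd implant with the calibrated parameter values and
inspect degradation, bone growth and ultrastructure at the explant
times:

```r
library(osteomg)
p  <- defaultParameters("Mg-10Gd")
tr <- simulateModel(p$remodelling, p$degradation,
                    p$ultrastructure[["002"]],
                    times = seq(0, 230, by = 0.5))
tr[tr$time %in% c(28, 84, 224), c("time", "Vloss", "H", "Cwidth", "L")]
#>     time  Vloss      H Cwidth      L
#> 57    28 0.2229 0.2788 0.1610 3.4322
#> 169   84 0.2959 0.3983 0.4034 3.4344
#> 449  224 0.3620 0.4508 0.4700 3.4408
computeLag(tr)
#> 14.7  (days)
```

Reading: by 4 weeks the implant has lost 22% of its volume and the
lattice spacing has contracted from the healthy 3.447 Å to 3.432 Å;
mineralization, delayed ~15 days by the Mg²⁺-driven inhibitor spike,
then catches up while the lattice recovers toward 3.447 Å as ion release
fades. Goodness-of-fit for any variable comes from `metricReport()`
(MAE, range-normalized RMSE, and the 1.96·σ/√n margin of error used as a
constant-width confidence ribbon).

Calibration runs through `stagedWorkflow()`: Ti fixes the shared bone
parameters, Mg-10Gd fixes the Mg coupling and ultrastructure rates, and
Mg-5Gd is predicted with everything frozen. `generateStudy()` produces
study-shaped synthetic datasets (sparse grids, 6 animals/time point,
10% CV) from known truth for end-to-end recovery experiments, and
`sobolAnalysis()` ranks parameter influence (first-order and total
Sobol indices, Saltelli design on a Sobol' sequence).

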