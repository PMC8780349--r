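---
title: "Age-dependent dermal absorption: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-dependent dermal absorption: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedperm)
```

## The problem

Neonatal and infant skin is anatomically immature: the stratum corneum (SC)
and viable epidermis are thinner than in adults, the dermis is a fraction of
its adult thickness, and surface hydration changes rapidly over the first
months of life.  Because the SC is the principal permeation barrier, these
differences translate into systematically higher percutaneous absorption in
young children — the reason topical exposures that are innocuous in adults
can be toxic in neonates.  `pedperm` implements a mechanistic workflow for
quantifying that difference: a three-layer Fickian skin permeation
simulator whose physiology matures with postnatal age, an adult calibration
step against in vitro permeation test (IVPT) data, and a Monte Carlo
extrapolation to pediatric ages.

## The permeation model

Skin is modelled as three stacked homogeneous layers — SC, viable epidermis
(ED), dermis (DE) — with thicknesses $h_{sc}, h_{ed}, h_{de}$, lumped
diffusivities $D_{sc}, D_{ed}, D_{de}$ (cm²/h) and water-referenced
partition coefficients $K_{sc/w}, K_{ed/w}, K_{de/w}$.  Transport follows
Fick's second law in each layer,

$$\frac{\partial c}{\partial t} = D \frac{\partial^2 c}{\partial x^2},$$

with flux continuity and partition equilibrium (continuity of the activity
$a = c/K$) at the layer interfaces, a well-mixed donor vehicle on top, and
a perfect-sink receptor below the dermis (receptor fluid chosen to mimic
dermal solubility and diffusivity, so no additional receptor resistance).
The reported outputs are the IVPT observables: the flux into the receptor
$y_J(t) = D_{de}\,\partial c/\partial x$ at the skin base (µg/cm²/h) and
its cumulative integral, the receptor accumulation $y_Q(t)$ (µg/cm²).

Numerically, each layer is discretised into finite-volume cells (15/15/30
by default), transport between adjacent cells is driven by activity
differences through harmonic-mean interface conductances, and the resulting
banded linear ODE system — donor state, cell amounts, receptor
accumulation — is integrated with the stiff `lsoda` solver (deSolve) at
relative tolerance $10^{-6}$.  The discretisation is verified in the test
suite against the single-membrane closed forms (steady flux $KDC/h$, lag
time $h^2/6D$, both within 2%) and against an independent spectral
(eigendecomposition) solution of the multilayer problem (within 1%);
doubling the grid changes the terminal flux by under 1%, and mass is
conserved to about $10^{-13}$ relative.

### Donor regimes

A scenario is *saturated* when the applied dose exceeds what the vehicle
can dissolve (`dose > solubility × depth`): undissolved material keeps the
donor activity pinned at the solubility for the whole run.  Otherwise the
donor is *finite*: well mixed, depleting, with concentration dose/depth.
The packaged buprenorphine and diamorphine buffer scenarios are saturated
(doses of 2656 and 53,100 µg/cm² against aqueous solubilities of 16.8 and
600 mg/L); phenobarbital in ethanol (78 µg/cm², 100 mg/mL solubility)
stays dissolved.

The donor depth deserves a note.  It only enters through the finite-regime
donor concentration and the saturation rule, but it is *not* absorbed by
the adult calibration: it moves the entire achievable (flux, accumulation)
frontier.  At a 1 mm donor depth the phenobarbital donor is so concentrated
that no SC parameter set inside the allowed uncertainty boxes reproduces
the observed adult flux and accumulation jointly (the implied diffusion lag
is several times too long); the frontier converges in the dilute-donor
limit, where the calibration becomes exact.  The default is therefore a
1 cm donor (≈1 mL/cm², an infinite-dose-style dissolved donor), set from
the adult calibration diagnostics.

### In vitro anatomy

The adult reference anatomy is a fully hydrated SC of 43 µm, a viable
epidermis of 60 µm (adult maximal epidermis scale) and a dermis of 500 µm.
The dermis value describes a *dermatomed* in vitro section, standard IVPT
practice, rather than the full anatomical dermis (~2500 µm).  This is a
deliberate choice: with a full-thickness dermis the model becomes
dermis-limited (for buprenorphine the dermis-limited flux ceiling falls
below the observed adult flux) and the dermis acts as a large reservoir
for finite doses — both at odds with the sensitivity structure of this
model family, in which the outputs are dominated by SC parameters.  With
the dermatomed default, the adult calibrations for both saturated-donor
compounds are exact and SC-dominated.  All three thicknesses are
configurable through `adult_reference()`.

## QSPR closures

Three uncertain SC parameters, the set fitted per compound, are tied to
physicochemistry by quantitative structure–property relationships:

* trans-bilayer permeability: $\log_{10} k_{trans} = -0.570 - 0.840\,MW^{1/3}$ (cm/s), uncertainty ±1.26;
* protein/water partition: $\log_{10} PC_{pro/w} = 0.27 \log K_{ow} + \log_{10} 5.4$, uncertainty ±0.32;
* lipid/water partition: $\log_{10} K_{lip/w} = 0.81 \log K_{ow} + \log_{10} 0.43$, uncertainty ±0.434.

The SC/water partition coefficient is a phase-volume-weighted sum over the
aqueous, protein and lipid phases of the fully hydrated SC ($\phi_w = 0.60$,
$\phi_{pro} = 0.325$, $\phi_{lip} = 0.075$, age-invariant):

$$K_{sc/w} = \phi_w \cdot hyd + \phi_{pro} PC_{pro/w} + \phi_{lip} K_{lip/w} f_{ni},$$

where $f_{ni}$ is the Henderson–Hasselbalch non-ionized fraction at the
vehicle pH, applied to the lipid phase only (the aqueous and protein phases
see total concentration).  The SC permeability closure treats the SC as
$N = 70$ lamellar bilayers in series,
$P_{sc} = k_{trans} K_{lip/w} / N$, and the lumped diffusivity follows as
$D_{sc} = P_{sc}\, h_{ref} / K_{sc/w}$ with $h_{ref}$ the *adult reference*
hydrated thickness.  Two consequences are intentional:

* $D_{sc}$ is an age-invariant material property; the steady-state flux
  then scales inversely with the actual SC thickness, which is the
  mechanism behind higher neonatal flux.  (Using the age-specific
  thickness in the closure would cancel thickness out of the steady-state
  flux entirely.)
* $f_{ni}$ does **not** appear in $P_{sc}$.  Partitioning into the lipid
  phase already carries the ionization penalty; applying it again to the
  translocation step would double-count it.  Concretely, the packaged
  buffer scenarios are at pH 4 while buprenorphine and diamorphine are
  bases (pKa 8.65, 7.83): with $f_{ni}$ (~$10^{-5}$–$10^{-4}$) inside
  $P_{sc}$, the nominal fluxes would sit 4–5 orders of magnitude below the
  observations, far beyond the reach of the ±1.26 log-unit fitting range.
  Equivalently, a saturated donor of an ionizable compound presents a
  constant free-form activity equal to the intrinsic (printed) aqueous
  solubility — the classic pH-partition argument — which is exactly how the
  saturated boundary is driven here.

The viable epidermis and dermis share an aqueous-diffusivity correlation
$\log_{10} D_{aq}(\text{cm}^2/\text{s}) = -4.15 - 0.655 \log_{10} MW$
divided by a tortuosity factor (default 3), and a common near-aqueous
partition coefficient (default 0.7).  Albumin binding is not modelled
separately; it is folded into that constant.

## Maturation functions

Each age-dependent parameter is expressed as a child:adult ratio versus
postnatal age (days), using one of three candidate forms:

* sigmoid: $a\,\mathrm{Age}/(b + \mathrm{Age}) + c$
* Hill: $a\,\mathrm{Age}^n/(b^n + \mathrm{Age}^n) + c$
* polynomial: $a\,\mathrm{Age}^n + b\,\mathrm{Age}^m + c$

The packaged defaults (`default_maturation_models()`) are:

| parameter | form | equation | cap age |
|---|---|---|---|
| SC thickness (model 2) | polynomial | $2.662\times10^{-7} Age^{1.878} + 0.724$ | 1604 d |
| epidermis | Hill | $(1-0.634)\,Age^{5.363}/(18.702^{5.363}+Age^{5.363}) + 0.634$ | none (asymptotic) |
| dermis | sigmoid | $(1.5-0.407)\,Age/(8974+Age) + 0.407$ | 9883 d |
| SC hydration | polynomial | $-0.344\,Age^{0.245} - 17.585\,Age^{-0.0171} + 18.530$ | 1182 d |

Beyond its cap age each ratio is exactly 1.  Implementation details worth
knowing:

* SC model 2 is the default; an alternative SC model 1 (fitted on a dataset
  including neonatal measurements that exceed adult values) sits behind
  `sc_model = 1`.
* The hydration polynomial diverges as Age → 0 through its negative
  exponent; it is evaluated at max(Age, 1 day), matching the domain of the
  data behind it.  The ratio exceeds 1 around one month of age (≈1.15 at
  30 days) — infant skin is transiently *more* hydrated than adult skin —
  and returns to 1 at the cap.
* The dermis formula evaluates to ≈0.98 at its cap, so the cap introduces a
  small deliberate jump; it is implemented exactly as printed rather than
  smoothed.
* In the in vitro evaluation mode the SC is taken as fully hydrated, so the
  hydration ratio is forced to 1 by default (`in_vitro_hydration = TRUE`);
  for in-vivo-style runs it scales the SC water phase fraction.

### Fitting and selection

`fit_maturation()` fits a candidate form to ratio-versus-age data by
unweighted nonlinear least squares on the ratio scale (no log transform, no
weights), using multi-start Levenberg–Marquardt from broad boxes
(age-scale parameters log-uniform on [1, 10⁴] days, offsets in [0, 2],
exponents in [0.01, 8], amplitudes uniform or sign-symmetric log-uniform).
`select_maturation_model()` scores candidate forms by leave-one-out
cross-validation and picks the lowest mean squared prediction error, with
ties broken by fewer parameters and then lower residual sum of squares;
the winner's cap age is found by root-solving the fitted curve against 1.
Root-solving the packaged SC model 2 coefficients gives 1597 days, which
agrees with the printed cap (1604) to 3 significant figures — the small
difference is printed-coefficient rounding.

The synthetic ratio generator (`generate_synthetic_ratios()`) emulates
literature child:adult ratio scatter as curve values plus additive
Gaussian noise floored at 0.01.  It reproduces the curve shapes and noise
magnitude, not the heteroscedasticity, age clustering or between-study
offsets of real literature data — so passing recovery tests demonstrate
estimator correctness, not robustness to real-data pathologies.  At the
test conditions (epidermis Hill curve, noise sd 0.05, 40 ages) the Hill
steepness is near the information limit: its single-replicate sampling
error is ~10–15%, so the recovery tests assert the median over 20
replicate datasets (observed median errors: 1.5% for $b$, 0.3% for $c$,
5% for $n$).

## Adult SC thickness uncertainty

The adult hydrated SC thickness is lognormal.  Its coefficient of
variation is estimated from 19 literature measurements of partially
hydrated SC thickness across anatomical sites (packaged fixture) under a
lognormal assumption, $cv = \sqrt{e^{s^2}-1}$ with $s^2$ the unbiased
log-variance: $cv = 0.431$.  Combining with the 43 µm hydrated mean gives
$\sigma^2 = \ln(1+cv^2) = 0.170$ and $\mu = \ln 43 - \sigma^2/2 = 3.68$.
All 19 rows are treated as independent values (including two forearm rows
from one study); pooling them differently would change the third decimal.

## Adult-to-child extrapolation

1. **Adult model.**  Age is set to 30 years (all maturation ratios 1).
2. **Calibration.**  The three uncertain SC parameters are fitted to the
   observed adult terminal flux and final receptor accumulation by
   minimising the equally weighted sum of squared relative errors, with
   box constraints at the printed uncertainty ranges, from 10 random
   starting points (L-BFGS-B; candidates are pre-screened with one cheap
   objective evaluation because much of the box is a dead plateau where no
   permeant reaches the receptor within the run).  Three parameters
   against two observations is deliberately under-determined: the contract
   is output matching, and among equally good optima the solution closest
   to the nominal QSPR values is kept.
3. **Pediatric Monte Carlo.**  At each requested postnatal age, 100
   simulations are run, each with an independent draw of the hydrated SC
   thickness from the adult lognormal scaled by the SC maturation ratio;
   epidermis and dermis thicknesses scale deterministically.  The reported
   prediction is the geometric mean of the terminal flux with an empirical
   2.5–97.5 percentile interval (the least-assumption reading of a
   "geometric mean with 95% CI" summary).

Prediction quality is scored as the fold error, predicted geometric mean
divided by observed flux.  Preterm subjects (gestational age < 37 weeks)
are simulated like term subjects of the same postnatal age by default — the
workflow carries no gestational-age physiology — and are flagged in the
evaluation records; an optional SC-thickness multiplier is exposed for
preterm sensitivity exploration.

Local sensitivity (`local_sensitivity()`) uses central-difference
normalized coefficients $S = (\Delta Y/Y)/(\Delta P/P)$ at ±10% for both
outputs over the nine lumped layer parameters; parameters whose
coefficient differs between a child age and the adult by ≥0.15 are flagged
age-sensitive (`age_differential_sensitivity()`).

## Problem sizes and numerical choices

The default study conditions are used throughout: 60 grid cells, 100 Monte
Carlo samples per age, 10 calibration starts, 20 (LOOCV: 8–30) fitting
starts.  The test suite runs the full three-compound evaluation at these
sizes; only the seed-determinism check uses reduced sizes (10 samples,
4 starts), since bit-reproducibility does not depend on the sample count.
Degenerate inputs are handled explicitly: zero dose returns identically
zero flux; a degenerate (point) calibration box returns the nominal
parameters; thickness draws are strictly positive by construction;
negative concentrations beyond integrator tolerance raise an error rather
than being silently clipped.

## Known limitations

* The SC is a homogeneous pseudo-phase; there is no brick-and-mortar
  corneocyte geometry, no separate corneocyte-phase transport, and no
  follicular shunt route.
* No metabolic clearance or skin blood flow: the model describes in vitro
  permeation, not in vivo bioavailability.
* Volatile vehicles are treated as non-volatile over the experiment
  (relevant to the ethanol scenario); evaporation dynamics are out of
  scope.
* Gestational age does not enter the physiology; preterm predictions are
  term-equivalent and should be read as preliminary.
* Only the SC thickness is sampled in the Monte Carlo step; population
  variability in other parameters is not represented, so the intervals
  quantify one (dominant) uncertainty source.
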