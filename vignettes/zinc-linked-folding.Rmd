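---
title: "Zinc-linked folding thermodynamics of the p53 DNA-binding domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zinc-linked folding thermodynamics of the p53 DNA-binding domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zincfold)
```

## The model

The p53 DNA-binding domain (DBD) folds around a single structural Zn²⁺ ion.
zincfold models the domain as a four-state equilibrium between unfolded (U),
native apo (N), native holo (N·Zn), and unfolded zinc-bound (U·Zn) species:

* `U ⇌ N`, with folding constant `K_apo = exp(+ΔG_apo/RT)`;
* `N + Zn ⇌ N·Zn`, with the femtomolar native-site dissociation constant
  `K_Zn`;
* `U + Zn ⇌ U·Zn`, one *average* low-affinity site with constant `K_Zn,U`.
  The unfolded chain may in reality expose more than one weak site; the
  model collapses them to a single site, which is the assumption under which
  all landscape quantities are computed.

At buffered free zinc `z` the populations follow the partition function
`Q = 1 + K_apo + K_apo·z/K_Zn + z/K_Zn,U`; the fraction of functional,
native zinc-bound protein is `F_holo = (K_apo·z/K_Zn)/Q`. This four-species
form is exact; it reduces to the three-term holo-fraction expression often
written with `1/K_apo` grouping when `K_apo ≪ 1` (the physiological regime),
because the bare `f_U` term is then negligible. We always use the exact
form.

The overall folding free energy under zinc linkage is

```
ΔG_fold(z) = ΔG_apo(T) − ΔG_Zn(z) + ΔG_Zn,U(z),
ΔG_site(z) = −RT ln(1 + z/K_d),
```

which plotted against log `z` is flat at `ΔG_apo`, deflects upward near
`K_Zn`, rises by RT per e-fold, and levels off near `K_Zn,U`. A pure
zinc-binding mutant shifts the deflection point without moving the
intercept; a pure stability mutant does the opposite.

Temperature enters through the Gibbs–Helmholtz stability curve

```
ΔG_apo(T) = ΔH_m (1 − T/T_m) − ΔC_p [(T_m − T) + T ln(T/T_m)],
```

a downward parabola whose width is set by `ΔC_p`. Combined with the linkage
model it yields the temperature × zinc energy landscape
(`landscape_grid()`), the package's central object.

### Sign convention

Stability free energies are stored **positive = folded state favoured**, so
`K_apo = exp(+ΔG/RT)`, zinc binding to the native site *raises* `ΔG_fold`,
and a destabilising mutation has `ΔΔG_apo > 0`. Reports and landscape
exports state this convention explicitly; all printed magnitudes match the
usual experimental reporting.

## Parameters and defaults

| Parameter | Meaning | Unit | Wild-type default |
|---|---|---|---|
| `ΔH_m` | unfolding enthalpy at `T_m` | kcal/mol | 171 |
| `T_m` | melting temperature | K | 300 |
| `ΔC_p` | heat-capacity change | kcal mol⁻¹ K⁻¹ | 7.0 |
| `K_Zn` | native-site Zn dissociation constant | M | 1.6e-15 (direct) or 7.0e-15 (linkage fit) |
| `K_Zn,U` | unfolded-site constant | M | 4.2e-8 |
| `m` | denaturation cooperativity | kcal mol⁻¹ M⁻¹ | 3.1 (urea), 7.0 (GdnHCl) |
| R | gas constant | kcal mol⁻¹ K⁻¹ | 1.9872e-3 |

`wt_dbd_params()` exposes both native-site constants because the direct
tyrosine-fluorescence titration and the zinc-linkage fit give slightly
different values; the direct value is the default and is what the energy
landscape uses. Temperatures convert with a 273.15 offset (37 °C =
310.15 K). Mutant parameter sets (`make_mutant_params()`) shift the whole
stability curve by the 10 °C `ΔΔG_apo` — i.e. the mutation is assumed not to
change `ΔH_m` or `ΔC_p` — keep `K_Zn,U`, and treat `K_Zn` as temperature
independent.

## Fitting stages

All nonlinear fits run through multi-start trust-region
Levenberg–Marquardt (minpack.lm) with analytic model functions, numeric
Jacobians, and column-equilibrated covariance (parameter scales range from
nanomolar amplitudes to log₁₀ constants, so the information matrix is
rescaled before inversion). Dissociation constants are always fitted as
log₁₀ K and reported on both scales with delta-method standard errors.

* **Melts** (`fit_lem_curve()`): two-state linear extrapolation with linear
  baselines. Baselines initialise from the terminal three points of each
  branch, the midpoint from the baseline-normalised half-crossing, and the
  m-value from the denaturant-specific prior (3.1 urea / 7.0 GdnHCl); five
  deterministic start scalings guard against baseline/transition local
  minima. Melts that never cross their midpoint inside the denaturant range
  are rejected as non-identifiable rather than extrapolated.
* **Pooled m** (`pool_m_values()`, `dg_from_cm()`): per-denaturant mean and
  standard error; `ΔG = C_m·m_pool` with quadrature error propagation.
* **Linkage profiles** (`fit_linkage_profile()`): weighted least squares
  (1/se² when stated errors are supplied) with `K_Zn,U` held at the
  competition-assay value. Profiles whose fitted rise is under 0.5 kcal/mol
  or whose log₁₀ `K_Zn` standard error exceeds 1.5 decades are flagged
  `k_zn_identifiable = FALSE` and only the plateau is interpreted — the
  behaviour needed for tyrosine-to-cysteine variants whose native-site
  titration cannot be measured.
* **Stability curves** (`fit_stability_curve()`): Gibbs–Helmholtz fit with
  `T_m` initialised from the warm-side zero crossing and a 3 × 3 start grid
  over `ΔH_m` and `ΔC_p`.
* **Binding** (`fit_single_site()`, `fit_hill()`, `fit_ic50()`,
  `fit_anisotropy_global()`): standard single-site, Hill, and empirical
  logistic forms. The logistic steepness is signed so
  indicator-displacement curves (falling signal) fit naturally, and the
  IC50 is the midpoint regardless of direction; an additive offset can be
  floated but defaults off. Anisotropy panels are fitted globally per
  oligonucleotide — one baseline, amplitude and Hill coefficient shared
  across mutants, one `K_DNA` per mutant — and fitted constants above the
  25 µM measurement floor are set to the floor and flagged; relative
  affinity tables propagate a "≤" qualifier for such entries.

### The competition analysis and the `y0` convention

`simulate_competition()` solves the exact three-component equilibrium
(indicator + unfolded protein competing for a limiting zinc pool) with full
depletion. The analysis route, in contrast, is the empirical logistic IC50
fit followed by the Munson–Rodbard depletion correction

```
K_i = IC50 / (1 + FZ3(y0+2)/(2K(y0+1)) + y0) − K·y0/(y0+2).
```

`y0` is the bound/free indicator ratio with no competitor. Under the
standard setup (30 nM FluoZin-3, 15 nM Zn, K = 15 nM) the *nominal*
convention sets `y0 = zn_total/K = 1`, ignoring depletion; the exact
bound/free ratio from the indicator quadratic is ≈ 0.414. Both modes are
exposed (`ki_from_ic50(..., y0 = "nominal"/"exact"/number)`); nominal is
the default because it is the established reporting convention for this
assay. The package's own tests quantify the consequence: running the exact
forward model through the logistic + nominal-y0 analysis recovers a 42 nM
competitor constant with a systematic ≈ −17 % bias (the test suite bounds it
at 25 %), while the exact-y0 mode removes most of that bias. Users
comparing absolute `K_Zn,U` values across methods should be aware the
convention, not the data, sets this offset.

## Outlier rejection

Assay curves occasionally contain gross artifacts (bubbles, mixing errors)
that would traditionally be screened by eye before refitting. zincfold
replaces that inspection with a deterministic two-stage rule
(`reject_outliers()`):

1. **Nomination.** Each point receives a leave-one-out *deletion* z-score:
   the model is refitted without it and the point's deviation from the
   deletion fit's prediction is scaled by the known measurement error (or
   the deletion fit's residual sd when no errors are given). Deletion
   residuals are used because an ordinary fit partially absorbs a gross
   point — internally studentized residuals are bounded by √(n−p) and
   cannot distinguish a fit-absorbed gross error from ordinary scatter.
   Points with z > 5 become candidates; the cut is deliberately a
   gross-anomaly threshold, far beyond plausible Gaussian extremes at
   typical curve sizes (8–20 points), so ordinary noise is essentially
   never nominated.
2. **Confirmation.** The model is refitted without the *whole* candidate
   set (one gross point must not contaminate the interval used to judge
   another), and each candidate is kept out only if it falls outside the
   Holm–Bonferroni-adjusted 95 % prediction interval of that suspect-free
   refit (the j-th of m candidates is tested at α = 0.05/(m−j+1)) *and* the
   exclusion lowers the average relative standard error of the fit
   parameters. Otherwise everything is restored. Nomination and
   confirmation iterate until stable, which resolves mutual masking between
   multiple gross points.

A detector must trade false alarms against misses: an "8σ" artifact whose
own noise realisation lands near 4σ is genuinely indistinguishable from an
extreme clean point. At the operating point above, the test suite measures
zero rejections across 400 clean simulated curves of two assay types and
≥ 95 % detection of 8σ injections (200 seeds each, single and paired), with
paired injections handled by the iterative re-nomination.

## Solvers

Two scalar equilibrium problems are solved by bracketed bisection on a log
concentration scale, bracket [1e-25 M, total], 200 iterations, relative
tolerance 1e-12: the closed-system zinc balance (`solve_closed_system()`,
residual `w + bound(w) − Zn_total`, monotone in `w`) and the
chelator-buffer speciation (`free_zinc()`, 1:1 binding per chelator).
Bisection is slower than Newton steps but convergence is guaranteed for
these monotone residuals, and both problems are far from any performance
budget. The closed-system solution is cross-checked in the tests against
the closed-form quadratic reduction of the same balance and against an
independent bisection oracle (< 1e-8 relative), and conservation residuals
above 1e-6 relative raise an error instead of returning silently.
`required_zn_total()` is a direct forward evaluation (no iteration) and
round-trips through `free_zinc()`.

Chelator conditional constants are inputs, not outputs: the shipped
`chelator_constants()` table carries representative near-neutral-pH values
for recipe design and simulation, and quantitative work should supply
constants for the actual pH and ionic strength. No proton/multi-metal
speciation model is implemented.

## What the synthetic data do and do not emulate

Each generator (`gen_melt_panel()`, `gen_titration()`, `gen_competition()`,
`gen_anisotropy_panel()`, `gen_stability_series()`,
`gen_linkage_profile()`) produces the corresponding assay table from the
forward model plus homoscedastic Gaussian noise, with the wild-type
parameter regime as default truth: 20-point urea melts with linear
baselines at 2 % amplitude noise, femtomolar titration grids spanning
1e-17–1e-13 M, the 30/15/15 nM competition setup, 5 nM–10 µM anisotropy
grids with a 50 nM labelled oligonucleotide design, and ten-temperature
stability series over 2–22 °C at 0.3 kcal/mol noise. Generators are
seed-deterministic (bit-identical tables for identical seeds, caller RNG
state untouched) and every generator's truth is recovered by its paired
fitting stage exactly at zero noise.

The generators do *not* emulate instrument-specific artifacts —
inner-filter effects, photobleaching, drift, heteroscedastic counting noise
(a σ ∝ signal option exists but is off by default), pipetting covariance
between points, or protein aggregation at warm temperatures. Passing
recovery tests on these simulations therefore demonstrates that the
estimators are correct and well calibrated for the stated noise model, not
that real curves of arbitrary quality will yield parameters at the quoted
precision.

Simulation sizes used by the test suite and the acceptance script — e.g.
500 stability-series replicates for the `ΔC_p` recovery distribution, 400
titrations for the Hill-coefficient median (a median must be resolved to
the width of its acceptance band), 200 seeds per arm for the outlier-rule
operating characteristics, 1e6 random draws for the species-fraction
invariants — were chosen so each statistic is estimated with sampling error
comfortably below the tolerance it is compared against.

## Classification

`classify_mutants()` applies fixed, strict thresholds to each variant's
(`ΔΔG_apo`, `K_Zn` fold-change) pair: > 1.0 kcal/mol destabilisation
and/or > 10-fold zinc-affinity loss partition variants into stability,
zinc-binding, mixed, or DNA-contact-candidate classes. Values exactly at a
threshold are *not* impaired (strict inequality). Variants whose `K_Zn`
cannot be measured are listed as stability class with an explicit caveat
flag, since a mixed mechanism cannot be excluded. The DNA-contact label
stays a *candidate* unless a relative `K_DNA` vector corroborates the loss
of DNA binding (10-fold, matching the zinc threshold's spirit) — binding
data, not the absence of thermodynamic impairment, is what confirms the
class. Classification is unit-invariant and deterministic;
`classification_report()` emits raw counts, the impaired fraction, and
scatter coordinates, and attempts no reconciliation beyond them.

## Known limitations

* Equilibrium only: unfolding/metal-exchange kinetics are out of scope.
* Two-state melts: three-state or aggregation-coupled unfolding is not
  modelled; the m-value constancy across zinc conditions is an input
  assumption, not a test the package performs.
* One average unfolded-state zinc site; landscapes at zinc concentrations
  far above `K_Zn,U` inherit that simplification.
* The closed-system route and the buffered route answer different
  questions at micromolar totals, where depletion is strong; the holo
  stability printed for the 10 °C equimolar condition is depletion-limited
  and is not expected to match no-depletion calculations.
* 3-D landscape rendering is left to the caller; the package exports long
  tables and a 2-D `autoplot()` raster.
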