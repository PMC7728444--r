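# zincfold

Equilibrium analysis of zinc-coupled protein folding for the p53
DNA-binding domain (DBD).

The DBD is only marginally stable at body temperature and requires a single
structural Zn²⁺ ion bound with femtomolar affinity to fold. zincfold
implements the four-state thermodynamic linkage model that couples folding
and metal binding — unfolded (U), native apo (N), native holo (N·Zn), and
zinc-bound unfolded (U·Zn) protein — together with every analysis stage
needed to parameterise it from bench assays and to project the resulting
temperature × zinc energy landscape. It is aimed at protein biophysicists
quantifying metal-linked stability, and at anyone classifying tumour-derived
p53 mutants by the mechanism of their loss of function.

## The model

Folding and binding are linked through

```
ΔG_fold(z) = ΔG_apo(T) − ΔG_Zn(z) + ΔG_Zn,U(z),     ΔG_site(z) = −RT ln(1 + z/K_d)
```

with the apo-state stability extrapolated in temperature by the
Gibbs–Helmholtz equation

```
ΔG_apo(T) = ΔH_m (1 − T/T_m) − ΔC_p [(T_m − T) + T ln(T/T_m)]
```

and the population of functional protein given by the four-state partition
function, `F_holo = (K_apo z/K_Zn) / (1 + K_apo + K_apo z/K_Zn + z/K_Zn,U)`.
All stabilities use one sign convention: positive = folded state favoured,
`K_apo = exp(+ΔG/RT)`.

Around that core the package provides, each as a data-frame-in /
tibble-out fitting stage with broom-style `tidy()`/`glance()` and
`autoplot()` methods:

* two-state linear-extrapolation melt fitting with pooled m-values
  (`fit_lem_curve()`, `pool_m_values()`, `dg_from_cm()`);
* zinc-linkage and Gibbs–Helmholtz regression with a deterministic
  prediction-interval outlier-rejection rule (`fit_linkage_profile()`,
  `fit_stability_curve()`, `reject_outliers()`);
* direct femtomolar titrations, Hill analysis, and FluoZin-3 competition
  with the Munson–Rodbard IC50→Ki correction (`fit_single_site()`,
  `fit_hill()`, `fit_ic50()`, `ki_from_ic50()`, `simulate_competition()`);
* global DNA-anisotropy fitting with a per-oligo linked Hill shape and the
  25 µM measurement floor (`fit_anisotropy_global()`,
  `kdna_relative_matrix()`);
* chelator-buffered free-zinc speciation and inverse recipe design
  (`free_zinc()`, `required_zn_total()`);
* energy-landscape grids and mutant classification (`landscape_grid()`,
  `make_mutant_params()`, `classify_mutants()`);
* seeded synthetic generators for every assay type, so the whole pipeline
  is testable against known ground truth (`gen_*()`).

## Worked example

```r
library(zincfold)

wt <- wt_dbd_params()
wt
#> <thermo_params> WT
#>   K_Zn   = 1.6e-15 M   K_Zn,U = 4.2e-08 M
#>   dH_m = 171 kcal/mol   T_m = 300 K   dC_p = 7 kcal/mol/K
#>   dG_apo(283.15 K) = 6.23 kcal/mol (positive = folded)

# populations at body temperature across the physiological free-zinc range
species_fractions(wt, zn_free = c(1e-11, 1e-10, 1e-9), temperature = 310.15)
#> # A tibble: 3 × 6
#>   temperature_K     zn_free_M   f_u        f_n  f_nzn    f_uzn
#> 1          310. 0.00000000001 0.929 0.0000113  0.0707 0.000221
#> 2          310. 0.0000000001  0.567 0.00000691 0.432  0.00135
#> 3          310. 0.000000001   0.116 0.00000141 0.881  0.00276
```

`f_nzn` is the functional holo fraction: at a typical intracellular free
zinc concentration of 100 pM the wild-type domain is almost evenly split
between folded-with-zinc (0.43) and unfolded — it sits on the edge of its
own folding transition, and a tenfold change of free zinc in either
direction pushes it to 0.88 or 0.07.

Fitting a noisy simulated stability-vs-zinc profile recovers the generating
parameters with standard errors:

```r
lp  <- gen_linkage_profile(noise_sd = 0.2, seed = 42)   # truth: 6.23 kcal/mol, 7.0e-15 M
fit <- fit_linkage_profile(lp$data, k_zn_u = 4.2e-8)
tidy(fit)
#> # A tibble: 3 × 3
#>   term        estimate std.error
#> 1 dg_apo      6.28e+ 0  9.14e- 2
#> 2 log10_k_zn -1.43e+ 1  1.03e- 1
#> 3 k_zn        5.12e-15  1.22e-15
```

And the closed-system solver connects the landscape to holo-protein
denaturation measurements:

```r
cs <- solve_closed_system(wt, 310.15, protein_total = 2.5e-6, zn_total = 2.5e-6)
dg_holo_theory(cs$f_nzn, 310.15)
#> [1] -2.813368   # kcal/mol
```

See `vignettes/zinc-linked-folding.Rmd` for the model's assumptions, the
numerical choices behind each fitting stage, and what the synthetic-data
tests do and do not demonstrate.

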