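# Seeded synthetic-data generators for every assay the pipeline consumes.
# Each generator returns list(data = <assay table>, truth = <parameters>),
# is bit-reproducible for a given seed, and its truth is recoverable by the
# paired fitting stage (exactly at zero noise). Defaults mirror the measured
# wild-type DBD regime so simulations double as documentation.

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simulate denaturation melt curves
#'
#' Generates two-state linear-extrapolation melts with linear baselines and
#' homoscedastic Gaussian noise. When `zn_free` values and `params` are
#' given, each curve's stability follows the linkage model
#' ([dg_fold()]) at its zinc concentration, emulating a zinc-conditioned
#' melt series; otherwise all curves share `dg`.
#'
#' @param n_curves Number of melts (ignored when `zn_free` is given: one
#'   curve per zinc concentration).
#' @param dg Apo stability (kcal/mol), used when `zn_free` is NULL.
#' @param m m-value (kcal mol-1 M-1).
#' @param baselines Named list `a_n`, `b_n`, `a_u`, `b_u` (signal units).
#' @param zn_free Optional vector of buffered free zinc concentrations (M).
#' @param params Optional [thermo_params()] driving the zinc dependence.
#' @param temperature Temperature (K).
#' @param denaturant Grid of denaturant concentrations (M).
#' @param noise_sd Gaussian noise standard deviation, as a fraction of the
#'   baseline amplitude (default 0.02).
#' @param denaturant_kind "urea" or "GdnHCl" label.
#' @param seed Integer seed (NULL uses the current RNG state).
#' @return List `data` (tibble: curve_id, denaturant_M, signal,
#'   temperature_K, zn_free_M, denaturant_kind) and `truth`.
#' @export
gen_melt_panel <- function(n_curves = 1, dg = 6.4, m = 3.1,
                           baselines = list(a_n = 1.0, b_n = -0.02,
                                            a_u = 0.35, b_u = -0.01),
                           zn_free = NULL, params = NULL,
                           temperature = 283.15,
                           denaturant = seq(0, 8, length.out = 20),
                           noise_sd = 0.02,
                           denaturant_kind = "urea", seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (!is.null(zn_free)) {
    if (is.null(params)) abort("`params` is required with `zn_free`.")
    dgs <- dg_fold(params, zn_free, temperature)
    n_curves <- length(zn_free)
  } else {
    dgs <- rep(dg, n_curves)
    zn_free <- rep(NA_real_, n_curves)
  }
  amp <- abs(baselines$a_n - baselines$a_u)
  with_seed_if(seed, {
    rows <- purrr::map(seq_len(n_curves), function(i) {
      p <- c(a_n = baselines$a_n, b_n = baselines$b_n,
             a_u = baselines$a_u, b_u = baselines$b_u,
             dg = dgs[i], m = m)
      mu <- lem_signal(p, tibble(x = denaturant, temperature = temperature))
      tibble(curve_id = sprintf("melt%03d", i),
             denaturant_M = denaturant,
             signal = mu + stats::rnorm(length(denaturant),
                                        sd = noise_sd * amp),
             temperature_K = temperature, zn_free_M = zn_free[i],
             denaturant_kind = denaturant_kind)
    })
    list(data = dplyr::bind_rows(rows),
         truth = list(dg = dgs, m = m, baselines = baselines,
                      zn_free = zn_free, temperature = temperature,
                      noise_sd = noise_sd))
  })
}

#' Simulate a direct zinc titration
#'
#' Single-site (or Hill) binding curve over a buffered free-zinc grid in the
#' femtomolar regime of the native DBD site.
#'
#' @param k_zn True dissociation constant (M), default 1.6e-15.
#' @param n Hill coefficient (1 = independent sites).
#' @param f0,amplitude Baseline and amplitude (signal units).
#' @param zn_free Free zinc grid (M), default 12 points over 1e-17..1e-13.
#' @param noise_sd Gaussian noise sd in signal units (default 0.01).
#' @param seed Integer seed.
#' @return List `data` (tibble: zn_free_M, signal) and `truth`.
#' @export
gen_titration <- function(k_zn = 1.6e-15, n = 1, f0 = 1, amplitude = 0.5,
                          zn_free = 10^seq(-17, -13, length.out = 12),
                          noise_sd = 0.01, seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  p <- c(f0 = f0, amplitude = amplitude, log10_k = log10(k_zn), n = n)
  mu <- hill_fn(p, tibble(x = zn_free))
  with_seed_if(seed, {
    list(data = tibble(zn_free_M = zn_free,
                       signal = mu + stats::rnorm(length(mu), sd = noise_sd)),
         truth = list(k_zn = k_zn, n = n, f0 = f0, amplitude = amplitude,
                      noise_sd = noise_sd))
  })
}

#' Simulate a FluoZin-3 competition curve
#'
#' Uses the exact forward equilibrium ([simulate_competition()]) with
#' explicit zinc depletion, then adds Gaussian noise to the indicator
#' signal.
#'
#' @param k_protein True competitor (unfolded DBD) zinc dissociation
#'   constant (M), default 42e-9.
#' @param setup A [competition_setup()].
#' @param protein_grid Competitor totals (M).
#' @param noise_sd Noise sd as a fraction of the zero-protein signal
#'   (default 0.02).
#' @param seed Integer seed.
#' @return List `data` (tibble from [simulate_competition()] with noisy
#'   `signal`) and `truth`.
#' @export
gen_competition <- function(k_protein = 42e-9,
                            setup = competition_setup(),
                            protein_grid = 10^seq(-9, -4.5, length.out = 16),
                            noise_sd = 0.02, seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  clean <- simulate_competition(setup, protein_grid, k_protein)
  s0 <- simulate_competition(setup, 0, k_protein)$signal
  with_seed_if(seed, {
    noisy <- dplyr::mutate(clean, signal = .data$signal +
                             stats::rnorm(dplyr::n(), sd = noise_sd * s0))
    list(data = noisy,
         truth = list(k_protein = k_protein, setup = setup,
                      signal_zero_protein = s0, noise_sd = noise_sd))
  })
}

#' Simulate a DNA-anisotropy mutant panel
#'
#' Hill-shaped anisotropy curves over a protein-concentration grid for a
#' panel of oligos x mutants with a shared baseline, amplitude and Hill
#' coefficient and per-(oligo, mutant) K_DNA truth.
#'
#' @param kdna_truth Tibble with columns `oligo`, `mutant`, `k_dna_M`.
#'   Defaults to a 3-oligo x 3-mutant panel spanning 0.1-30 uM with one
#'   non-binder (K_DNA 1e-3 M, beyond the 25 uM floor).
#' @param n Shared Hill coefficient (default 1).
#' @param r0,amplitude Baseline and amplitude (anisotropy units).
#' @param protein_grid Protein totals (M), default 12 points 5e-9..1e-5.
#' @param noise_sd Gaussian noise sd in anisotropy units (default 0.003).
#' @param seed Integer seed.
#' @return List `data` (tibble: oligo, mutant, protein_M, anisotropy) and
#'   `truth`.
#' @export
gen_anisotropy_panel <- function(kdna_truth = NULL, n = 1, r0 = 0.06,
                                 amplitude = 0.16,
                                 protein_grid = 10^seq(log10(5e-9), -5,
                                                       length.out = 12),
                                 noise_sd = 0.003, seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (is.null(kdna_truth)) {
    kdna_truth <- tidyr::expand_grid(oligo = c("RE1", "RE2", "RE3"),
                                     mutant = c("WT", "mutA", "mutB"))
    kdna_truth$k_dna_M <- c(1e-7, 3e-7, 1e-3,
                            5e-7, 1.5e-6, 1e-3,
                            2e-6, 3e-5, 1e-3)
  }
  with_seed_if(seed, {
    rows <- purrr::pmap(kdna_truth, function(oligo, mutant, k_dna_M) {
      p <- c(f0 = r0, amplitude = amplitude, log10_k = log10(k_dna_M), n = n)
      mu <- hill_fn(p, tibble(x = protein_grid))
      tibble(oligo = oligo, mutant = mutant, protein_M = protein_grid,
             anisotropy = mu + stats::rnorm(length(mu), sd = noise_sd))
    })
    list(data = dplyr::bind_rows(rows),
         truth = list(kdna = kdna_truth, n = n, r0 = r0,
                      amplitude = amplitude, noise_sd = noise_sd))
  })
}

#' Simulate a stability-vs-temperature series
#'
#' Gibbs-Helmholtz stability points over the cold working range of the DBD
#' (2-22 degrees C by default), with Gaussian noise and optional injected
#' gross outliers for exercising the rejection rule.
#'
#' @param temperatures Temperatures (K), default 10 points 275.15-295.15.
#' @param dh_m,t_m,dc_p True Gibbs-Helmholtz parameters (defaults 171 /
#'   300 / 7.0).
#' @param noise_sd Gaussian noise sd (kcal/mol), default 0.3.
#' @param n_outliers Number of gross outliers to inject (default 0).
#' @param outlier_sigma Outlier displacement in units of `noise_sd`
#'   (default 8); alternating sign, applied to evenly spaced interior
#'   points.
#' @param seed Integer seed.
#' @return List `data` (tibble: temperature_K, dg, se, outlier_truth) and
#'   `truth`.
#' @export
gen_stability_series <- function(temperatures = seq(275.15, 295.15,
                                                    length.out = 10),
                                 dh_m = 171, t_m = 300, dc_p = 7.0,
                                 noise_sd = 0.3, n_outliers = 0,
                                 outlier_sigma = 8, seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  mu <- gibbs_helmholtz_dg(temperatures, dh_m, t_m, dc_p)
  nT <- length(temperatures)
  with_seed_if(seed, {
    dg <- mu + stats::rnorm(nT, sd = noise_sd)
    is_out <- rep(FALSE, nT)
    if (n_outliers > 0) {
      idx <- unique(round(seq(2, nT - 1, length.out = n_outliers)))
      shift <- outlier_sigma * max(noise_sd, 0.05) *
        rep_len(c(1, -1), length(idx))
      dg[idx] <- dg[idx] + shift
      is_out[idx] <- TRUE
    }
    list(data = tibble(temperature_K = temperatures, dg = dg,
                       se = noise_sd, outlier_truth = is_out),
         truth = list(dh_m = dh_m, t_m = t_m, dc_p = dc_p,
                      noise_sd = noise_sd))
  })
}

#' Simulate a dG vs free-zinc linkage profile
#'
#' Stability points over a log zinc grid following [dg_fold()] with
#' Gaussian noise, emulating the pooled-melt stability profiles used for
#' linkage fitting.
#'
#' @param params A [thermo_params()] (default the wild type with the
#'   linkage-fit K_Zn of 7.0e-15 M).
#' @param zn_free Zinc grid (M), default 12 points 1e-16..1e-12.
#' @param temperature Temperature (K), default 283.15.
#' @param noise_sd Gaussian noise sd (kcal/mol), default 0.2.
#' @param n_outliers,outlier_sigma Optional injected outliers as in
#'   [gen_stability_series()].
#' @param seed Integer seed.
#' @return List `data` (tibble: zn_free_M, dg, se, outlier_truth) and
#'   `truth`.
#' @export
gen_linkage_profile <- function(params = wt_dbd_params("linkage"),
                                zn_free = 10^seq(-16, -12, length.out = 12),
                                temperature = 283.15, noise_sd = 0.2,
                                n_outliers = 0, outlier_sigma = 8,
                                seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  mu <- dg_fold(params, zn_free, temperature)
  nz <- length(zn_free)
  with_seed_if(seed, {
    dg <- mu + stats::rnorm(nz, sd = noise_sd)
    is_out <- rep(FALSE, nz)
    if (n_outliers > 0) {
      idx <- unique(round(seq(2, nz - 1, length.out = n_outliers)))
      shift <- outlier_sigma * max(noise_sd, 0.05) *
        rep_len(c(1, -1), length(idx))
      dg[idx] <- dg[idx] + shift
      is_out[idx] <- TRUE
    }
    list(data = tibble(zn_free_M = zn_free, dg = dg, se = noise_sd,
                       outlier_truth = is_out),
         truth = list(dg_apo = dg_apo(params, temperature),
                      k_zn = params$k_zn, k_zn_u = params$k_zn_u,
                      temperature = temperature, noise_sd = noise_sd))
  })
}
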