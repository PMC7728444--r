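# Four-state zinc-linkage model: closed forms, closed-system solver,
# and energy-landscape grids.

#' Gibbs-Helmholtz stability free energy
#'
#' Evaluates the protein stability curve
#' dG(T) = dH_m (1 - T/T_m) - dC_p ((T_m - T) + T log(T/T_m)),
#' in the positive = folded-favoured convention. dG vanishes at `t_m`, is
#' maximal at T_s = T_m exp(-dH_m / (dC_p T_m)), and turns negative above
#' the melting temperature.
#'
#' @param temperature Absolute temperature(s), K.
#' @param dh_m Unfolding enthalpy at T_m (kcal/mol).
#' @param t_m Melting temperature (K).
#' @param dc_p Heat-capacity change of unfolding (kcal mol-1 K-1).
#' @return Stability free energy (kcal/mol), vectorised over `temperature`.
#' @examples
#' gibbs_helmholtz_dg(celsius_to_kelvin(c(10, 37)), 171, 300, 7.0)
#' @export
gibbs_helmholtz_dg <- function(temperature, dh_m, t_m, dc_p) {
  if (any(temperature <= 0)) abort("`temperature` must be positive (Kelvin).")
  if (any(t_m <= 0)) abort("`t_m` must be positive (Kelvin).")
  dh_m * (1 - temperature / t_m) -
    dc_p * ((t_m - temperature) + temperature * log(temperature / t_m))
}

#' Folding equilibrium constant from a stability free energy
#'
#' K_apo = \[N\]/\[U\] = exp(dG / RT) under the positive = folded-favoured
#' sign convention.
#'
#' @param dg_stab Stability free energy (kcal/mol).
#' @param temperature Absolute temperature (K).
#' @return Unitless equilibrium constant, vectorised.
#' @export
kapo_from_dg <- function(dg_stab, temperature) {
  exp(dg_stab / rt_kcal(temperature))
}

#' Zinc-binding free-energy term of the linkage model
#'
#' Returns -RT log(1 + zn_free / k_d), the free-energy contribution of a
#' single 1:1 zinc site with dissociation constant `k_d` at free zinc
#' concentration `zn_free`. Always <= 0; applied with the native-site K_Zn it
#' gives dG_Zn, with the unfolded-state K_Zn,U it gives dG_Zn,U.
#'
#' @param k_d Site dissociation constant (M), > 0.
#' @param zn_free Free zinc concentration (M), >= 0.
#' @param temperature Absolute temperature (K).
#' @return Free energy (kcal/mol), vectorised.
#' @export
zinc_linkage_dg <- function(k_d, zn_free, temperature) {
  if (any(k_d <= 0)) abort("`k_d` must be > 0.")
  if (any(zn_free < 0)) abort("`zn_free` must be non-negative.")
  -rt_kcal(temperature) * log1p(zn_free / k_d)
}

#' Overall folding free energy under the zinc-linkage model
#'
#' dG_fold = dG_apo(T) - dG_Zn + dG_Zn,U: zinc binding to the tight native
#' site stabilises (raises dG_fold, positive = folded favoured), binding to
#' the weak unfolded-state site destabilises. The curve vs log zinc has a
#' low-zinc plateau at dG_apo, deflects upward near K_Zn, and levels off
#' near K_Zn,U.
#'
#' @param params A [thermo_params()] object.
#' @param zn_free Buffered free zinc concentration(s), M.
#' @param temperature Absolute temperature (K); default the parameter set's
#'   reference temperature.
#' @return Folding free energy (kcal/mol), vectorised over `zn_free`.
#' @examples
#' wt <- wt_dbd_params("linkage")
#' dg_fold(wt, zn_free = 10^seq(-16, -7), temperature = 283.15)
#' @export
dg_fold <- function(params, zn_free, temperature = params$t_ref) {
  stopifnot(inherits(params, "thermo_params"))
  dg_apo(params, temperature) -
    zinc_linkage_dg(params$k_zn, zn_free, temperature) +
    zinc_linkage_dg(params$k_zn_u, zn_free, temperature)
}

#' Four-state species fractions (low-level, vectorised)
#'
#' Populations of the four species U, N, N.Zn, U.Zn given the apo stability,
#' the two site constants and free zinc, from the partition function
#' Q = 1 + K_apo + K_apo z / K_Zn + z / K_Zn,U (unfolded protein is assumed
#' to bind a single zinc ion).
#'
#' @param dg_stab Apo stability (kcal/mol, positive = folded favoured).
#' @param zn_free Free zinc (M).
#' @param k_zn,k_zn_u Site dissociation constants (M).
#' @param temperature Absolute temperature (K).
#' @return Tibble with columns `f_u`, `f_n`, `f_nzn`, `f_uzn`, each in
#'   \[0, 1\] and summing to 1.
#' @export
four_state_fractions <- function(dg_stab, zn_free, k_zn, k_zn_u, temperature) {
  if (any(zn_free < 0)) abort("`zn_free` must be non-negative.")
  if (any(k_zn <= 0) || any(k_zn_u <= 0)) abort("site constants must be > 0.")
  kapo <- kapo_from_dg(dg_stab, temperature)
  # divide through by the largest term to stay finite for extreme K_apo
  t_u <- rep_len(1, max(length(kapo), length(zn_free)))
  t_n <- rep_len(kapo, length(t_u))
  t_nzn <- t_n * rep_len(zn_free / k_zn, length(t_u))
  t_uzn <- rep_len(zn_free / k_zn_u, length(t_u))
  top <- pmax(t_u, t_n, t_nzn, t_uzn)
  q <- (t_u + t_n + t_nzn + t_uzn) / top
  tibble(f_u = t_u / top / q, f_n = t_n / top / q,
         f_nzn = t_nzn / top / q, f_uzn = t_uzn / top / q)
}

#' Species fractions for a parameter set at given conditions
#'
#' @param params A [thermo_params()] object.
#' @param zn_free Buffered free zinc concentration(s), M.
#' @param temperature Absolute temperature(s), K.
#' @return Tibble with the conditions and `f_u`, `f_n`, `f_nzn`, `f_uzn`;
#'   `f_nzn` is the fraction of native, zinc-bound protein (F_holo).
#' @examples
#' species_fractions(wt_dbd_params(), zn_free = c(1e-11, 1e-10, 1e-9),
#'                   temperature = 310.15)
#' @export
species_fractions <- function(params, zn_free, temperature = params$t_ref) {
  stopifnot(inherits(params, "thermo_params"))
  n <- max(length(zn_free), length(temperature))
  zn_free <- rep_len(zn_free, n)
  temperature <- rep_len(temperature, n)
  fr <- four_state_fractions(dg_apo(params, temperature), zn_free,
                             params$k_zn, params$k_zn_u, temperature)
  dplyr::bind_cols(tibble(temperature_K = temperature, zn_free_M = zn_free), fr)
}

#' Theoretical stability of the zinc-bound native state
#'
#' dG_holo,theory = -RT log(F_holo / (1 - F_holo)): converts a native
#' zinc-bound population into an apparent unfolding free energy comparable
#' with holo-protein denaturation measurements (negative when the holo state
#' dominates).
#'
#' @param f_holo Fraction of native zinc-bound protein, strictly in (0, 1).
#' @param temperature Absolute temperature (K).
#' @return Free energy (kcal/mol), vectorised.
#' @export
dg_holo_theory <- function(f_holo, temperature) {
  if (any(f_holo <= 0 | f_holo >= 1)) {
    abort("`f_holo` must lie strictly between 0 and 1.")
  }
  -rt_kcal(temperature) * log(f_holo / (1 - f_holo))
}

#' Equilibrium speciation of a closed protein/zinc system
#'
#' Solves for free zinc and the four protein species when total protein and
#' total zinc are fixed (no chelator buffering), i.e. under the two mass
#' balances protein = U + N + N.Zn + U.Zn and zinc = free + N.Zn + U.Zn and
#' the three equilibrium constants. The residual is monotone in free zinc, so
#' the root is found by bracketed bisection on a log scale (bracket
#' \[1e-25 M, zn_total\], relative tolerance 1e-12, at most 200 iterations).
#'
#' @param params A [thermo_params()] object.
#' @param temperature Absolute temperature (K).
#' @param protein_total Total protein concentration (M).
#' @param zn_total Total zinc concentration (M).
#' @return One-row tibble: `zn_free_M`, `f_u`, `f_n`, `f_nzn`, `f_uzn`, and
#'   the conservation residual `resid_rel` (relative to `zn_total`).
#' @examples
#' solve_closed_system(wt_dbd_params(), 310.15, 2.5e-6, 2.5e-6)
#' @export
solve_closed_system <- function(params, temperature, protein_total, zn_total) {
  stopifnot(inherits(params, "thermo_params"))
  if (protein_total < 0 || zn_total < 0) abort("totals must be non-negative.")
  if (zn_total == 0) {
    fr <- four_state_fractions(dg_apo(params, temperature), 0,
                               params$k_zn, params$k_zn_u, temperature)
    return(dplyr::bind_cols(tibble(zn_free_M = 0), fr,
                            tibble(resid_rel = 0)))
  }
  bound_zn <- function(w) {
    fr <- four_state_fractions(dg_apo(params, temperature), w,
                               params$k_zn, params$k_zn_u, temperature)
    protein_total * (fr$f_nzn + fr$f_uzn)
  }
  resid <- function(w) w + bound_zn(w) - zn_total
  lo <- log10(1e-25)
  hi <- log10(zn_total)
  if (resid(10^lo) > 0) {
    # protein binds essentially nothing; free zinc ~ total
    w <- zn_total
  } else {
    for (i in seq_len(200)) {
      mid <- (lo + hi) / 2
      if (resid(10^mid) > 0) hi <- mid else lo <- mid
      if ((hi - lo) < 1e-12 / log(10)) break
    }
    w <- 10^((lo + hi) / 2)
  }
  fr <- four_state_fractions(dg_apo(params, temperature), w,
                             params$k_zn, params$k_zn_u, temperature)
  res <- abs(w + protein_total * (fr$f_nzn + fr$f_uzn) - zn_total) / zn_total
  if (res > 1e-6) {
    abort(sprintf(paste0("closed-system solver did not converge: relative ",
                         "zinc-conservation residual %.3g at zn_free = %.3g M"),
                  res, w))
  }
  dplyr::bind_cols(tibble(zn_free_M = w), fr, tibble(resid_rel = res))
}

#' Temperature/zinc energy-landscape grid
#'
#' Evaluates the fraction of native zinc-bound protein (F_holo) over a grid
#' of temperatures and log10 free zinc concentrations.
#'
#' @param params A [thermo_params()] object.
#' @param temperatures Ascending temperatures (K).
#' @param log_zn Ascending log10 free zinc concentrations (log10 M).
#' @return Long-format tibble with columns `temperature_K`,
#'   `log10_zn_free_M`, `f_holo`, of class `landscape_grid`.
#' @examples
#' grid <- landscape_grid(wt_dbd_params(), seq(276, 320, by = 2),
#'                        seq(-16, -6, by = 0.25))
#' @export
landscape_grid <- function(params, temperatures, log_zn) {
  stopifnot(inherits(params, "thermo_params"))
  if (length(temperatures) == 0 || length(log_zn) == 0) {
    abort("grids must be non-empty.")
  }
  if (is.unsorted(temperatures, strictly = TRUE) ||
      is.unsorted(log_zn, strictly = TRUE)) {
    abort("grids must be strictly ascending.")
  }
  grid <- tidyr::expand_grid(temperature_K = temperatures,
                             log10_zn_free_M = log_zn)
  fr <- four_state_fractions(dg_apo(params, grid$temperature_K),
                             10^grid$log10_zn_free_M,
                             params$k_zn, params$k_zn_u, grid$temperature_K)
  out <- dplyr::mutate(grid, f_holo = fr$f_nzn)
  class(out) <- c("landscape_grid", class(out))
  attr(out, "variant") <- params$name
  out
}
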