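# Chemical denaturation melts: two-state linear-extrapolation fits, pooled
# m-values, and regression of dG profiles against zinc (linkage model) and
# temperature (Gibbs-Helmholtz).

lem_signal <- function(p, data) {
  # p: a_n, b_n, a_u, b_u, dg, m ; data$x = denaturant (M)
  rt <- R_KCAL * data$temperature[1]
  k <- exp((p[["dg"]] - p[["m"]] * data$x) / rt)  # [N]/[U] at this urea
  fn <- k / (1 + k)
  (p[["a_n"]] + p[["b_n"]] * data$x) * fn +
    (p[["a_u"]] + p[["b_u"]] * data$x) * (1 - fn)
}

#' Fit a denaturation melt to the two-state linear extrapolation model
#'
#' Fits fluorescence signal vs denaturant concentration to a two-state
#' unfolding transition with linear native and unfolded baselines:
#' the native fraction is 1 / (1 + exp(-(dG - m x) / RT)) and the observed
#' signal interpolates between the two baselines. Reports the stability dG
#' (kcal/mol), the cooperativity m-value (kcal mol-1 M-1), the midpoint
#' C_m = dG / m (M) with a delta-method standard error, and the baseline
#' coefficients. Initial values come from the terminal points of each
#' baseline and the signal mid-crossing, with a denaturant-specific m prior
#' (3.1 for urea, 7.0 for GdnHCl) and a small deterministic multi-start grid.
#'
#' @param data Data frame with columns `denaturant_M` (or `x`) and `signal`
#'   (or `y`); at least 8 points spanning both baselines.
#' @param denaturant_kind `"urea"` (default) or `"GdnHCl"`; sets the m-value
#'   prior used for initialisation only.
#' @param temperature Temperature of the melt (K), default 283.15.
#' @return Object of class `lem_fit` (also `zf_fit`); see [tidy.zf_fit()].
#'   `tidy()` includes the derived `c_m` row.
#' @examples
#' sim <- gen_melt_panel(n_curves = 1, noise_sd = 0, seed = 1)
#' fit <- fit_lem_curve(sim$data)
#' tidy(fit)
#' @export
fit_lem_curve <- function(data, denaturant_kind = c("urea", "GdnHCl"),
                          temperature = 283.15) {
  denaturant_kind <- match.arg(denaturant_kind)
  d <- standardise_xy(data, x_names = c("x", "denaturant_M", "denaturant"),
                      y_names = c("y", "signal"))
  if (nrow(d) < 8) abort("a melt needs at least 8 points.")
  if (any(d$x < 0)) abort("denaturant concentrations must be non-negative.")
  d$temperature <- temperature
  m_prior <- if (denaturant_kind == "urea") 3.1 else 7.0

  # baselines from the terminal 3 points of each branch
  d <- dplyr::arrange(d, .data$x)
  nb <- coef(lm(y ~ x, data = head(d, 3)))
  ub <- coef(lm(y ~ x, data = tail(d, 3)))
  # midpoint from the crossing of the baseline-normalised signal
  f_app <- (d$y - (ub[1] + ub[2] * d$x)) /
    ((nb[1] + nb[2] * d$x) - (ub[1] + ub[2] * d$x))
  cm0 <- tryCatch(stats::approx(f_app, d$x, xout = 0.5, ties = mean)$y,
                  error = function(e) NA_real_)
  if (is.na(cm0)) cm0 <- median(d$x)
  base_start <- c(a_n = unname(nb[1]), b_n = unname(nb[2]),
                  a_u = unname(ub[1]), b_u = unname(ub[2]))
  starts <- lapply(c(1, 0.7, 1.4, 0.5, 2), function(f) {
    c(base_start, dg = m_prior * f * cm0, m = m_prior * f)
  })
  ans <- zf_nls(d, starts, lem_signal)
  par <- ans$par
  if (par[["m"]] <= 0) abort("fitted m-value is not positive; no transition identified within the denaturant range.")
  refit <- function(dd) fit_lem_curve(dd, denaturant_kind = denaturant_kind,
                                      temperature = temperature)
  fit <- new_zf_fit(d, par, lem_signal, refit, "lem_fit",
                    extra = list(denaturant_kind = denaturant_kind,
                                 temperature = temperature))
  # derived midpoint C_m = dg/m with delta-method SE
  V <- fit$vcov[c("dg", "m"), c("dg", "m")]
  g <- c(1 / par[["m"]], -par[["dg"]] / par[["m"]]^2)
  fit$derived <- tibble(term = "c_m",
                        estimate = par[["dg"]] / par[["m"]],
                        std.error = sqrt(drop(t(g) %*% V %*% g)))
  if (fit$derived$estimate < min(d$x) || fit$derived$estimate > max(d$x)) {
    abort("fitted midpoint lies outside the denaturant range; transition not identifiable.")
  }
  fit
}

#' Fit every melt in a table of curves
#'
#' Groups a long assay table by `curve_id`, fits each melt with
#' [fit_lem_curve()], and returns one row per curve.
#'
#' @param data Data frame with columns `curve_id`, `denaturant_M`, `signal`,
#'   and optionally `temperature_K`, `zn_free_M`, `denaturant_kind`.
#' @return Tibble with per-curve `dg`, `m_value`, `c_m` (each with standard
#'   errors), the curve metadata, and the `lem_fit` object in a list column.
#' @export
fit_melt_curves <- function(data) {
  if (!"curve_id" %in% names(data)) data$curve_id <- "curve1"
  if (!"denaturant_kind" %in% names(data)) data$denaturant_kind <- "urea"
  if (!"temperature_K" %in% names(data)) data$temperature_K <- 283.15
  dplyr::group_by(data, .data$curve_id) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_lem_curve(d, denaturant_kind = d$denaturant_kind[1],
                           temperature = d$temperature_K[1])
      td <- tidy(fit)
      pick <- function(t) td$estimate[td$term == t]
      pick_se <- function(t) td$std.error[td$term == t]
      tibble(dg = pick("dg"), se_dg = pick_se("dg"),
             m_value = pick("m"), se_m = pick_se("m"),
             c_m = pick("c_m"), se_cm = pick_se("c_m"),
             temperature_K = d$temperature_K[1],
             zn_free_M = if ("zn_free_M" %in% names(d)) d$zn_free_M[1]
                         else NA_real_,
             denaturant_kind = d$denaturant_kind[1],
             fit = list(fit))
    }) |>
    dplyr::ungroup()
}

#' Pool m-values across melts
#'
#' The cooperativity m-value is poorly determined per curve; averaging it
#' over many melts (separately per denaturant) and recomputing each curve's
#' dG as C_m times the pooled m sharpens the stability estimates.
#'
#' @param fits Data frame with a `m_value` column (e.g. from
#'   [fit_melt_curves()]) and optionally `denaturant_kind`.
#' @return Tibble with one row per denaturant: `denaturant_kind`, `m_pool`
#'   (mean), `se` (standard error of the mean), `n`.
#' @export
pool_m_values <- function(fits) {
  if (nrow(fits) == 0) abort("no fits to pool.")
  if (!"denaturant_kind" %in% names(fits)) fits$denaturant_kind <- "urea"
  dplyr::summarise(
    dplyr::group_by(fits, .data$denaturant_kind),
    m_pool = mean(.data$m_value),
    se = if (dplyr::n() > 1) sd(.data$m_value) / sqrt(dplyr::n()) else 0,
    n = dplyr::n(), .groups = "drop")
}

#' Stability from the denaturation midpoint and a pooled m-value
#'
#' dG = C_m * m_pool, with the standard error propagated in quadrature:
#' se(dG)^2 = (m_pool se_cm)^2 + (C_m se_m)^2.
#'
#' @param c_m Denaturation midpoint(s), M.
#' @param m_pool Pooled m-value (kcal mol-1 M-1).
#' @param se_cm,se_m Standard errors (defaults 0).
#' @return Tibble with columns `dg`, `se` (kcal/mol).
#' @export
dg_from_cm <- function(c_m, m_pool, se_cm = 0, se_m = 0) {
  if (any(c_m <= 0) || any(m_pool <= 0)) abort("inputs must be positive.")
  tibble(dg = c_m * m_pool,
         se = sqrt((m_pool * se_cm)^2 + (c_m * se_m)^2))
}

linkage_fn_factory <- function(k_zn_u, temperature) {
  function(p, data) {
    dg_apo <- p[["dg_apo"]]
    k_zn <- 10^p[["log10_k_zn"]]
    dg_apo - zinc_linkage_dg(k_zn, data$x, temperature) +
      zinc_linkage_dg(k_zn_u, data$x, temperature)
  }
}

#' Fit a dG vs free-zinc profile to the linkage model
#'
#' Weighted nonlinear least squares of stability points against
#' dG_fold(z) = dG_apo - dG_Zn(z) + dG_Zn,U(z) with the unfolded-site
#' constant fixed (from the competition assay). Returns the apo stability
#' (the low-zinc plateau) and the native-site K_Zn (the deflection point);
#' K_Zn is fitted as log10 K and reported on both scales. Profiles that never
#' deflect within the zinc range (total rise under 0.5 kcal/mol or a K_Zn
#' standard error above 1.5 log units) are flagged non-identifiable and
#' refitted for the plateau only.
#'
#' @param data Data frame with columns `zn_free_M` (or `x`), `dg` (or `y`)
#'   and optionally `se` (kcal/mol; used as 1/se^2 weights).
#' @param k_zn_u Unfolded-state zinc dissociation constant (M), held fixed.
#' @param temperature Temperature of the profile (K), default 283.15.
#' @return Object of class `linkage_fit`; `tidy()` reports `dg_apo`,
#'   `log10_k_zn` and the derived `k_zn`. Field `k_zn_identifiable` records
#'   whether the deflection was measurable.
#' @examples
#' wt <- wt_dbd_params("linkage")
#' prof <- tibble::tibble(zn_free_M = 10^seq(-16, -12, 0.5),
#'                        dg = dg_fold(wt, 10^seq(-16, -12, 0.5)))
#' tidy(fit_linkage_profile(prof, k_zn_u = wt$k_zn_u))
#' @export
fit_linkage_profile <- function(data, k_zn_u, temperature = 283.15) {
  d <- standardise_xy(data, x_names = c("x", "zn_free_M", "zn_free"),
                      y_names = c("y", "dg"))
  if (nrow(d) < 5) abort("need at least 5 stability points.")
  pos <- d$x[d$x > 0]
  if (length(pos) < 2 || diff(range(log10(pos))) < 2) {
    abort("points must span at least 2 log units of free zinc.")
  }
  known_sigma <- FALSE
  if ("se" %in% names(d) && all(is.finite(d$se)) && all(d$se > 0)) {
    d$w <- 1 / d$se^2
    known_sigma <- TRUE
  }
  fn <- linkage_fn_factory(k_zn_u, temperature)
  dg0 <- mean(head(d$y[order(d$x)], 3))
  lk_grid <- seq(log10(min(pos)) - 1, log10(max(pos)), length.out = 5)
  starts <- lapply(lk_grid, function(lk) c(dg_apo = dg0, log10_k_zn = lk))
  ans <- zf_nls(d, starts, fn)
  refit <- function(dd) fit_linkage_profile(dd, k_zn_u = k_zn_u,
                                            temperature = temperature)
  fit <- new_zf_fit(d, ans$par, fn, refit, "linkage_fit",
                    extra = list(k_zn_u = k_zn_u, temperature = temperature,
                                 known_sigma = known_sigma))
  rise <- max(fitted(fit)) - min(fitted(fit))
  se_lk <- zf_se(fit)[["log10_k_zn"]]
  fit$k_zn_identifiable <- rise >= 0.5 && se_lk <= 1.5
  if (!fit$k_zn_identifiable) {
    warn("no deflection within the zinc range: K_Zn is non-identifiable; reporting the dG_apo plateau only.")
  }
  k_zn <- 10^fit$par[["log10_k_zn"]]
  fit$derived <- tibble(term = "k_zn", estimate = k_zn,
                        std.error = se_lk * log(10) * k_zn)
  fit
}

gh_fn <- function(p, data) {
  gibbs_helmholtz_dg(data$x, p[["dh_m"]], p[["t_m"]], p[["dc_p"]])
}

#' Fit a stability-vs-temperature series to the Gibbs-Helmholtz equation
#'
#' Nonlinear least squares of dG(T) points against the stability curve to
#' recover the unfolding enthalpy dH_m, melting temperature T_m, and
#' heat-capacity change dC_p. T_m is initialised from the dG = 0 crossing of
#' a local linear trend and the other parameters from a small deterministic
#' start grid.
#'
#' @param data Data frame with columns `temperature_K` (or `x`), `dg` (or
#'   `y`), optionally `se` (weights 1/se^2); at least 6 temperatures.
#' @return Object of class `stability_fit`; `tidy()` reports `dh_m`, `t_m`,
#'   `dc_p`.
#' @examples
#' sim <- gen_stability_series(noise_sd = 0, seed = 1)
#' tidy(fit_stability_curve(sim$data))
#' @export
fit_stability_curve <- function(data) {
  d <- standardise_xy(data, x_names = c("x", "temperature_K", "temperature"),
                      y_names = c("y", "dg"))
  if (nrow(d) < 6) abort("need at least 6 temperatures.")
  known_sigma <- FALSE
  if ("se" %in% names(d) && all(is.finite(d$se)) && all(d$se > 0)) {
    d$w <- 1 / d$se^2
    known_sigma <- TRUE
  }
  # T_m init: extrapolate the warm-side linear trend to dG = 0
  warm <- tail(dplyr::arrange(d, .data$x), 4)
  sl <- coef(lm(y ~ x, data = warm))
  tm0 <- if (is.finite(sl[2]) && sl[2] < 0) -sl[1] / sl[2] else max(d$x) + 10
  tm0 <- min(max(tm0, max(d$x) + 0.5), max(d$x) + 60)
  starts <- list()
  for (dh in c(100, 171, 250)) for (dcp in c(3, 7, 11)) {
    starts[[length(starts) + 1]] <- c(dh_m = dh, t_m = tm0, dc_p = dcp)
  }
  ans <- zf_nls(d, starts, gh_fn,
                lower = c(dh_m = 1, t_m = min(d$x), dc_p = 0),
                upper = c(dh_m = 2000, t_m = 600, dc_p = 100))
  refit <- function(dd) fit_stability_curve(dd)
  new_zf_fit(d, ans$par, gh_fn, refit, "stability_fit",
             extra = list(known_sigma = known_sigma))
}
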