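# Thermodynamic parameter sets for one protein variant.

#' Thermodynamic parameters of one DBD variant
#'
#' Bundles the full four-state parameter set: apo-state folding stability,
#' zinc dissociation constants of the native site (`k_zn`) and of the average
#' unfolded-state site (`k_zn_u`), and the Gibbs-Helmholtz temperature
#' dependence (`dh_m`, `t_m`, `dc_p`). Stability free energies follow a
#' single sign convention throughout the package: positive = folded state
#' favoured, so `K_apo = exp(+dG/RT)`.
#'
#' Either the Gibbs-Helmholtz triple (`dh_m`, `t_m`, `dc_p`) or a fixed
#' reference stability `dg_apo_ref` at `t_ref` must be supplied. With the
#' triple, stability is temperature dependent; with only `dg_apo_ref` it is
#' treated as constant (valid near `t_ref`).
#'
#' @param name Variant label.
#' @param k_zn Native-site zinc dissociation constant K_Zn (M).
#' @param k_zn_u Unfolded-state zinc dissociation constant K_Zn,U (M).
#' @param dh_m Unfolding enthalpy at the melting temperature (kcal/mol).
#' @param t_m Melting temperature (K).
#' @param dc_p Unfolding heat-capacity change (kcal mol-1 K-1).
#' @param dg_apo_ref Apo-state stability at `t_ref` (kcal/mol, positive =
#'   folded favoured). Computed from the Gibbs-Helmholtz triple when omitted.
#' @param t_ref Reference temperature (K), default 283.15 K (10 degrees C).
#' @param ddg_shift Destabilisation relative to the parent curve (kcal/mol),
#'   subtracted from the stability at every temperature. Used by
#'   [make_mutant_params()]; leave at 0 for measured variants.
#' @return An object of class `thermo_params`.
#' @seealso [wt_dbd_params()], [make_mutant_params()], [dg_apo()]
#' @examples
#' wt <- thermo_params("WT", k_zn = 1.6e-15, k_zn_u = 4.2e-8,
#'                     dh_m = 171, t_m = 300, dc_p = 7.0)
#' dg_apo(wt, celsius_to_kelvin(c(10, 37)))
#' @export
thermo_params <- function(name, k_zn, k_zn_u,
                          dh_m = NA_real_, t_m = NA_real_, dc_p = NA_real_,
                          dg_apo_ref = NA_real_, t_ref = 283.15,
                          ddg_shift = 0) {
  if (!is.numeric(k_zn) || k_zn <= 0) abort("`k_zn` must be > 0.")
  if (!is.numeric(k_zn_u) || k_zn_u <= 0) abort("`k_zn_u` must be > 0.")
  if (k_zn >= k_zn_u) {
    abort("`k_zn` must be smaller than `k_zn_u` (native site binds tighter).")
  }
  has_gh <- !is.na(dh_m) && !is.na(t_m) && !is.na(dc_p)
  if (has_gh) {
    if (t_m <= 0) abort("`t_m` must be positive (Kelvin).")
    if (dh_m <= 0) abort("`dh_m` must be positive.")
    if (dc_p < 0) abort("`dc_p` must be non-negative.")
  } else if (is.na(dg_apo_ref)) {
    abort("Supply either (`dh_m`, `t_m`, `dc_p`) or `dg_apo_ref`.")
  }
  if (t_ref <= 0) abort("`t_ref` must be positive (Kelvin).")
  obj <- structure(
    list(name = as.character(name), k_zn = k_zn, k_zn_u = k_zn_u,
         dh_m = dh_m, t_m = t_m, dc_p = dc_p,
         dg_apo_ref = dg_apo_ref, t_ref = t_ref, ddg_shift = ddg_shift),
    class = "thermo_params"
  )
  if (has_gh && is.na(dg_apo_ref)) {
    obj$dg_apo_ref <- dg_apo(obj, t_ref)
  }
  obj
}

#' Wild-type DBD parameter set
#'
#' Convenience constructor for the wild-type p53 DNA-binding domain:
#' Gibbs-Helmholtz parameters dH_m = 171 kcal/mol, T_m = 300 K,
#' dC_p = 7.0 kcal mol-1 K-1, unfolded-site affinity K_Zn,U = 42 nM, and a
#' native-site K_Zn of 1.6 fM (direct tyrosine-fluorescence titration) or
#' 7.0 fM (zinc-linkage fit), selectable via `k_zn_source`.
#'
#' @param k_zn_source `"direct"` (1.6e-15 M, default, used for landscapes) or
#'   `"linkage"` (7.0e-15 M).
#' @return A [thermo_params()] object.
#' @export
wt_dbd_params <- function(k_zn_source = c("direct", "linkage")) {
  k_zn_source <- match.arg(k_zn_source)
  k_zn <- switch(k_zn_source, direct = 1.6e-15, linkage = 7.0e-15)
  thermo_params("WT", k_zn = k_zn, k_zn_u = 4.2e-8,
                dh_m = 171, t_m = 300, dc_p = 7.0)
}

#' Derive a mutant parameter set from the wild type
#'
#' Builds a mutant landscape parameter set by shifting the wild-type
#' stability curve down by the 10 degree C stability loss `ddg_apo` at every
#' temperature and substituting the mutant native-site `k_zn`. K_Zn is
#' treated as temperature independent and K_Zn,U and the Gibbs-Helmholtz
#' temperature dependence are inherited unchanged from the wild type.
#'
#' @param wt_params Wild-type [thermo_params()].
#' @param name Mutant label.
#' @param ddg_apo Stability loss dG_apo(WT) - dG_apo(mut) at the reference
#'   temperature (kcal/mol; positive = destabilised).
#' @param k_zn Mutant native-site zinc dissociation constant (M); defaults to
#'   the wild-type value.
#' @return A [thermo_params()] object.
#' @examples
#' wt <- wt_dbd_params()
#' v272m <- make_mutant_params(wt, "V272M", ddg_apo = 2.0)
#' @export
make_mutant_params <- function(wt_params, name, ddg_apo = 0,
                               k_zn = wt_params$k_zn) {
  stopifnot(inherits(wt_params, "thermo_params"))
  if (k_zn <= 0) abort("`k_zn` must be > 0.")
  thermo_params(name, k_zn = k_zn, k_zn_u = wt_params$k_zn_u,
                dh_m = wt_params$dh_m, t_m = wt_params$t_m,
                dc_p = wt_params$dc_p,
                dg_apo_ref = if (is.na(wt_params$dh_m))
                  wt_params$dg_apo_ref - ddg_apo else NA_real_,
                t_ref = wt_params$t_ref,
                ddg_shift = wt_params$ddg_shift + ddg_apo)
}

#' Apo-state folding stability at temperature T
#'
#' Evaluates dG_apo(T) for a variant (kcal/mol, positive = folded favoured):
#' the Gibbs-Helmholtz curve shifted by the variant's `ddg_shift` when the
#' temperature parameters are present, otherwise the fixed reference value.
#'
#' @param params A [thermo_params()] object.
#' @param temperature Absolute temperature(s) in K.
#' @return Numeric vector of stabilities (kcal/mol).
#' @export
dg_apo <- function(params, temperature) {
  stopifnot(inherits(params, "thermo_params"))
  if (any(temperature <= 0)) abort("`temperature` must be positive (Kelvin).")
  base <- if (!is.na(params$dh_m)) {
    gibbs_helmholtz_dg(temperature, params$dh_m, params$t_m, params$dc_p)
  } else {
    rep(params$dg_apo_ref + params$ddg_shift, length(temperature))
  }
  base - params$ddg_shift
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("<thermo_params> %s\n", x$name))
  cat(sprintf("  K_Zn   = %.3g M   K_Zn,U = %.3g M\n", x$k_zn, x$k_zn_u))
  if (!is.na(x$dh_m)) {
    cat(sprintf("  dH_m = %.3g kcal/mol   T_m = %.4g K   dC_p = %.3g kcal/mol/K\n",
                x$dh_m, x$t_m, x$dc_p))
  }
  cat(sprintf("  dG_apo(%.2f K) = %.3g kcal/mol (positive = folded)",
              x$t_ref, dg_apo(x, x$t_ref)))
  if (x$ddg_shift != 0) cat(sprintf("   [ddG shift %.3g]", x$ddg_shift))
  cat("\n")
  invisible(x)
}
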