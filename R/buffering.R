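# Chelator-buffered free-zinc speciation and inverse recipe design.

#' Representative conditional Zn2+ dissociation constants of common chelators
#'
#' A small lookup of conditional (pH-corrected) dissociation constants for
#' chelators routinely used to buffer free zinc near neutral pH. These are
#' representative values around pH 7.0-7.4 intended for recipe design and
#' simulation; for quantitative work supply your own conditional constant for
#' the exact pH and ionic strength of the assay.
#'
#' @return Tibble with columns `label`, `k_cond_M`, `note`.
#' @export
chelator_constants <- function() {
  tibble(
    label = c("EDTA", "EGTA", "HEDTA", "NTA", "citrate"),
    k_cond_M = c(10^-13.6, 10^-8.9, 10^-10.6, 10^-7.6, 10^-4.7),
    note = rep("representative conditional Kd near pH 7.0-7.4", 5)
  )
}

check_mix <- function(mix) {
  if (!is.data.frame(mix)) abort("`mix` must be a data frame.")
  if (nrow(mix) == 0) return(invisible(mix))
  if (!all(c("k_cond_M", "total_M") %in% names(mix))) {
    abort("`mix` needs columns `k_cond_M` and `total_M`.")
  }
  if (any(mix$k_cond_M <= 0)) abort("conditional constants must be > 0.")
  if (any(mix$total_M < 0)) abort("chelator totals must be non-negative.")
  invisible(mix)
}

#' Free zinc concentration of a chelator/ZnCl2 mixture
#'
#' Solves the 1:1 speciation mass balance
#' zn_total = zn_free + sum_i total_i * zn_free / (k_cond_i + zn_free)
#' for the unique free zinc concentration, by bracketed bisection on a log
#' scale (bracket \[1e-25 M, zn_total\], relative tolerance 1e-12). Protein is
#' excluded from the balance (chelator is assumed in large excess).
#'
#' @param mix Data frame of chelator entries with columns `k_cond_M`
#'   (conditional Zn2+ dissociation constant, M) and `total_M` (total
#'   chelator, M); optionally `label`. An empty mix returns `zn_total`.
#' @param zn_total Total zinc (M).
#' @return Free zinc concentration (M).
#' @examples
#' mix <- tibble::tibble(label = "EGTA-like", k_cond_M = 1e-9, total_M = 2e-3)
#' free_zinc(mix, zn_total = 1e-3)
#' @export
free_zinc <- function(mix, zn_total) {
  check_mix(mix)
  if (length(zn_total) != 1 || zn_total < 0) {
    abort("`zn_total` must be a single non-negative number.")
  }
  if (nrow(mix) == 0 || zn_total == 0) return(zn_total)
  bound <- function(w) sum(mix$total_M * w / (mix$k_cond_M + w))
  resid <- function(w) w + bound(w) - zn_total
  lo <- log10(1e-25); hi <- log10(zn_total)
  if (resid(10^lo) > 0) return(zn_total)
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (resid(10^mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) < 1e-12 / log(10)) break
  }
  10^((lo + hi) / 2)
}

#' Total zinc needed to reach a target free-zinc concentration
#'
#' Inverse of [free_zinc()]: given the chelator mix, the total zinc that
#' buffers free zinc at `target_zn_free` follows directly from the forward
#' mass balance (no iteration needed).
#'
#' @param mix Chelator data frame as in [free_zinc()] (zinc-free recipe).
#' @param target_zn_free Desired free zinc concentration (M), > 0.
#' @return Total zinc to add (M). Round-trips through [free_zinc()].
#' @examples
#' mix <- tibble::tibble(k_cond_M = 1e-9, total_M = 2e-3)
#' required_zn_total(mix, 1e-12)   # ~2 uM
#' @export
required_zn_total <- function(mix, target_zn_free) {
  check_mix(mix)
  if (any(target_zn_free <= 0)) abort("`target_zn_free` must be > 0.")
  vapply(target_zn_free, function(w) {
    if (nrow(mix) == 0) return(w)
    w + sum(mix$total_M * w / (mix$k_cond_M + w))
  }, numeric(1))
}

#' Free-zinc table for a grid of buffer recipes
#'
#' Convenience wrapper evaluating [free_zinc()] for several total-zinc
#' additions to one chelator mix, e.g. to design a titration series.
#'
#' @param mix Chelator data frame as in [free_zinc()].
#' @param zn_totals Numeric vector of total zinc concentrations (M).
#' @return Tibble with columns `zn_total_M`, `zn_free_M`.
#' @export
buffer_grid <- function(mix, zn_totals) {
  tibble(zn_total_M = zn_totals,
         zn_free_M = vapply(zn_totals, function(z) free_zinc(mix, z),
                            numeric(1)))
}
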