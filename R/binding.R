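# Zinc-binding assays: direct titrations (single-site and Hill), FluoZin-3
# competition with the Munson-Rodbard IC50-to-Ki correction, and global
# DNA-anisotropy fitting.

single_site_fn <- function(p, data) {
  k <- 10^p[["log10_k"]]
  p[["f0"]] + p[["amplitude"]] * data$x / (k + data$x)
}

hill_fn <- function(p, data) {
  k <- 10^p[["log10_k"]]
  zn <- (data$x / k)^p[["n"]]
  p[["f0"]] + p[["amplitude"]] * zn / (1 + zn)
}

binding_starts <- function(d, with_n = FALSE) {
  f0 <- min(d$y)
  amp <- max(d$y) - min(d$y)
  pos <- d$x[d$x > 0]
  half <- tryCatch(
    stats::approx(d$y, d$x, xout = f0 + amp / 2, ties = mean)$y,
    error = function(e) NA_real_)
  lk0 <- if (is.finite(half) && half > 0) log10(half) else
    stats::median(log10(pos))
  lapply(c(0, -1, 1), function(off) {
    st <- c(f0 = f0, amplitude = amp, log10_k = lk0 + off)
    if (with_n) st <- c(st, n = 1)
    st
  })
}

finish_binding_fit <- function(d, ans, fn, refit, subclass) {
  fit <- new_zf_fit(d, ans$par, fn, refit, subclass)
  k <- 10^fit$par[["log10_k"]]
  se_lk <- zf_se(fit)[["log10_k"]]
  fit$derived <- tibble(term = "k_d", estimate = k,
                        std.error = se_lk * log(10) * k)
  rng <- range(d$x[d$x > 0])
  if (k < rng[1] / 50 || k > rng[2] * 50) {
    abort("fitted dissociation constant falls far outside the titration range; transition not identifiable.")
  }
  fit
}

#' Fit a direct titration to the single-site binding equation
#'
#' F = F0 + A z / (K + z) with z the buffered free ligand concentration.
#' The dissociation constant is fitted as log10 K; `tidy()` adds the
#' natural-scale `k_d` via the delta method.
#'
#' @param data Data frame with columns `zn_free_M` (or `x`) and `signal`
#'   (or `y`); at least 6 points spanning the transition.
#' @return Object of class `binding_fit`.
#' @examples
#' sim <- gen_titration(noise_sd = 0, seed = 1)
#' tidy(fit_single_site(sim$data))
#' @export
fit_single_site <- function(data) {
  d <- standardise_xy(data, x_names = c("x", "zn_free_M", "x_M"),
                      y_names = c("y", "signal"))
  if (nrow(d) < 6) abort("need at least 6 points.")
  if (any(d$x < 0)) abort("concentrations must be non-negative.")
  ans <- zf_nls(d, binding_starts(d), single_site_fn)
  finish_binding_fit(d, ans, single_site_fn,
                     function(dd) fit_single_site(dd), "binding_fit")
}

#' Fit a titration to the Hill binding equation
#'
#' F = F0 + A z^n / (K^n + z^n). With `n` fixed at 1 this reduces to
#' [fit_single_site()]; a free `n` measures apparent cooperativity (n = 1
#' for independent sites).
#'
#' @inheritParams fit_single_site
#' @return Object of class `hill_fit` with terms `f0`, `amplitude`,
#'   `log10_k`, `n` and derived `k_d`.
#' @export
fit_hill <- function(data) {
  d <- standardise_xy(data, x_names = c("x", "zn_free_M", "x_M"),
                      y_names = c("y", "signal"))
  if (nrow(d) < 6) abort("need at least 6 points.")
  if (any(d$x < 0)) abort("concentrations must be non-negative.")
  ans <- zf_nls(d, binding_starts(d, with_n = TRUE), hill_fn,
                lower = c(f0 = -Inf, amplitude = -Inf, log10_k = -30,
                          n = 0.05),
                upper = c(f0 = Inf, amplitude = Inf, log10_k = 3, n = 10))
  finish_binding_fit(d, ans, hill_fn,
                     function(dd) fit_hill(dd), "hill_fit")
}

#' Competition assay setup
#'
#' Totals and indicator affinity of a FluoZin-3 competition experiment.
#'
#' @param fz3_total Total indicator concentration (M).
#' @param zn_total Total zinc (M).
#' @param k_fz3 Indicator-zinc dissociation constant (M).
#' @return A list of class `competition_setup`.
#' @export
competition_setup <- function(fz3_total = 30e-9, zn_total = 15e-9,
                              k_fz3 = 15e-9) {
  if (fz3_total <= 0 || zn_total <= 0 || k_fz3 <= 0) {
    abort("all setup concentrations must be > 0.")
  }
  structure(list(fz3_total = fz3_total, zn_total = zn_total, k_fz3 = k_fz3),
            class = "competition_setup")
}

#' Exact forward model of an indicator competition curve
#'
#' For each competitor (protein) total, solves the full three-component
#' equilibrium Zn + FZ3 = FZ3.Zn (K = `k_fz3`) and Zn + P = P.Zn
#' (K = `k_protein`) with explicit zinc depletion, and reports the
#' indicator-bound zinc as the signal. This is the depletion-exact
#' counterpart to the empirical logistic/Munson-Rodbard analysis and is used
#' both to generate synthetic competition data and to quantify the
#' approximation error of that analysis.
#'
#' @param setup A [competition_setup()].
#' @param protein_grid Competitor total concentrations (M), >= 0.
#' @param k_protein Competitor-zinc dissociation constant (M), > 0.
#' @return Tibble with `protein_total_M`, `x` (log10 protein, -Inf at 0),
#'   `zn_free_M`, `fz3_zn_M`, and `signal` (= `fz3_zn_M`).
#' @examples
#' simulate_competition(competition_setup(), 10^seq(-9, -4), 42e-9)
#' @export
simulate_competition <- function(setup, protein_grid, k_protein) {
  stopifnot(inherits(setup, "competition_setup"))
  if (k_protein <= 0) abort("`k_protein` must be > 0.")
  if (any(protein_grid < 0)) abort("protein totals must be non-negative.")
  w <- vapply(protein_grid, function(pt) {
    f <- function(z) {
      z + setup$fz3_total * z / (setup$k_fz3 + z) +
        pt * z / (k_protein + z) - setup$zn_total
    }
    uniroot(f, lower = 1e-30, upper = setup$zn_total, tol = 1e-30)$root
  }, numeric(1))
  fz3zn <- setup$fz3_total * w / (setup$k_fz3 + w)
  tibble(protein_total_M = protein_grid,
         x = log10(protein_grid), zn_free_M = w,
         fz3_zn_M = fz3zn, signal = fz3zn)
}

ic50_fn <- function(p, data) {
  p[["offset"]] + p[["amplitude"]] /
    (1 + exp((p[["ic50_log10"]] - data$x) / p[["b"]]))
}

#' Fit a competition curve to the empirical logistic (IC50) form
#'
#' F = A / (1 + exp((IC50 - x) / b)) with x = log10 competitor
#' concentration. The steepness `b` is signed, so curves that fall with
#' increasing competitor (the usual indicator-displacement direction) fit
#' with b < 0; IC50 is the midpoint either way. An additive baseline offset
#' can optionally be floated.
#'
#' @param data Data frame with columns `x` (log10 M; or `protein_total_M`
#'   in M, converted internally) and `signal` (or `y`). Zero-competitor rows
#'   are dropped (log undefined).
#' @param float_offset Also fit an additive offset (default FALSE).
#' @return Object of class `ic50_fit`; `tidy()` reports `ic50_log10`,
#'   `amplitude`, `b`, optionally `offset`, and the derived molar `ic50`.
#' @export
fit_ic50 <- function(data, float_offset = FALSE) {
  if ("protein_total_M" %in% names(data) && !"x" %in% names(data)) {
    data$x <- log10(data$protein_total_M)
  }
  d <- standardise_xy(data[is.finite(data$x), ],
                      x_names = "x", y_names = c("y", "signal"))
  if (nrow(d) < 5) abort("need at least 5 finite points.")
  amp <- max(d$y) - min(d$y)
  dir_down <- coef(lm(y ~ x, data = d))[2] < 0
  mid <- tryCatch(stats::approx(d$y, d$x, xout = min(d$y) + amp / 2,
                                ties = mean)$y,
                  error = function(e) stats::median(d$x))
  starts <- lapply(c(0.3, 0.6, 1.2), function(b0) {
    c(offset = if (dir_down) min(d$y) else min(d$y),
      amplitude = amp, ic50_log10 = mid, b = if (dir_down) -b0 else b0)
  })
  fn <- ic50_fn
  if (!float_offset) {
    fn <- function(p, data) ic50_fn(c(p, offset = 0), data)
    starts <- lapply(starts, function(s) s[setdiff(names(s), "offset")])
  }
  ans <- zf_nls(d, starts, fn)
  if (ans$par[["ic50_log10"]] < min(d$x) - 1 ||
      ans$par[["ic50_log10"]] > max(d$x) + 1) {
    abort("midpoint outside the titration range; IC50 not identifiable.")
  }
  fit <- new_zf_fit(d, ans$par, fn,
                    function(dd) fit_ic50(dd, float_offset = float_offset),
                    "ic50_fit")
  ic50 <- 10^fit$par[["ic50_log10"]]
  fit$derived <- tibble(term = "ic50", estimate = ic50,
                        std.error = zf_se(fit)[["ic50_log10"]] * log(10) *
                          ic50)
  fit
}

#' Competitor Ki from an IC50 by the Munson-Rodbard correction
#'
#' Converts a competition IC50 into the competitor's dissociation constant
#' with the depletion-aware Munson-Rodbard solution of the Cheng-Prusoff
#' problem:
#' Ki = IC50 / (1 + FZ3 (y0 + 2) / (2 K (y0 + 1)) + y0) - K y0 / (y0 + 2),
#' where FZ3 is total indicator, K its zinc dissociation constant, and y0
#' the bound/free indicator ratio without competitor. `y0` may be given as
#' `"nominal"` (zn_total / k_fz3, ignoring depletion -- unity under the
#' standard 15 nM Zn / 15 nM K setup), `"exact"` (from the closed-form
#' indicator-zinc quadratic with depletion), or a number.
#'
#' @param ic50 Fitted IC50 (M), or an `ic50_fit` object.
#' @param setup A [competition_setup()].
#' @param y0 `"nominal"` (default), `"exact"`, or a numeric value.
#' @return Tibble with `ic50_M`, `y0`, `k_i_M`, and `valid` (FALSE when the
#'   correction exceeds the IC50 and the result is non-physical).
#' @export
ki_from_ic50 <- function(ic50, setup, y0 = c("nominal", "exact")) {
  stopifnot(inherits(setup, "competition_setup"))
  if (inherits(ic50, "ic50_fit")) {
    ic50 <- 10^ic50$par[["ic50_log10"]]
  }
  if (any(ic50 <= 0)) abort("`ic50` must be > 0.")
  if (is.character(y0)) {
    y0 <- match.arg(y0)
    y0 <- switch(y0, nominal = setup$zn_total / setup$k_fz3,
                 exact = y0_exact(setup))
  }
  if (y0 < 0) abort("`y0` must be non-negative.")
  k <- setup$k_fz3
  ki <- ic50 / (1 + setup$fz3_total * (y0 + 2) / (2 * k * (y0 + 1)) + y0) -
    k * y0 / (y0 + 2)
  valid <- ki > 0
  if (any(!valid)) {
    warn("Munson-Rodbard correction exceeds the IC50; Ki flagged invalid.")
  }
  tibble(ic50_M = ic50, y0 = y0, k_i_M = ki, valid = valid)
}

#' Bound/free indicator ratio without competitor (exact)
#'
#' Solves the 1:1 indicator-zinc quadratic with depletion and returns
#' bound/free FZ3 at zero competitor. Under the standard setup (30 nM FZ3,
#' 15 nM Zn, K = 15 nM) this evaluates to about 0.414, not 1; the nominal
#' convention is retained as the default of [ki_from_ic50()] nonetheless.
#'
#' @param setup A [competition_setup()].
#' @return Numeric scalar, bound/free indicator ratio.
#' @export
y0_exact <- function(setup) {
  stopifnot(inherits(setup, "competition_setup"))
  f <- setup$fz3_total; z <- setup$zn_total; k <- setup$k_fz3
  s <- f + z + k
  cplx <- (s - sqrt(s^2 - 4 * f * z)) / 2
  cplx / (f - cplx)
}

# global anisotropy model: shared r0/A/n per oligo, one log10 K per mutant
aniso_fn <- function(p, data) {
  lk <- p[paste0("lk_", data$mutant_idx)]
  zn <- (data$x / 10^lk)^p[["n"]]
  p[["r0"]] + p[["amplitude"]] * zn / (1 + zn)
}

#' Global Hill fit of DNA-anisotropy panels
#'
#' For each oligonucleotide, fits all mutants' anisotropy curves jointly to
#' r = r0 + A x^n / (K_DNA^n + x^n), linking the baseline, amplitude, and
#' Hill parameter across mutants and floating one K_DNA per mutant. Fitted
#' K_DNA values above the measurement floor are set to the floor and
#' flagged (no measurable transition). Oligos with a single mutant fall back
#' to a per-curve fit with a warning.
#'
#' @param data Data frame with columns `oligo`, `mutant`, `protein_M` (or
#'   `x_M`/`x`) and `anisotropy` (or `y`); >= 6 points per mutant.
#' @param floor_M Upper measurable limit for K_DNA (M), default 25e-6.
#' @return Object of class `anisotropy_fit`: a list with `kdna` (tibble
#'   oligo x mutant with `k_dna_M`, `se`, `floor_flag`, shared `hill_n`,
#'   `amplitude`, `r0`) and the per-oligo `zf_fit` objects in `fits`.
#' @examples
#' sim <- gen_anisotropy_panel(seed = 1)
#' fit <- fit_anisotropy_global(sim$data)
#' fit$kdna
#' @export
fit_anisotropy_global <- function(data, floor_M = 25e-6) {
  need <- c("oligo", "mutant")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns `oligo` and `mutant`.")
  }
  xn <- intersect(c("x", "protein_M", "x_M"), names(data))[1]
  yn <- intersect(c("y", "anisotropy"), names(data))[1]
  if (is.na(xn) || is.na(yn)) {
    abort("`data` needs protein concentration and anisotropy columns.")
  }
  out_rows <- list()
  fits <- list()
  for (og in unique(data$oligo)) {
    dd <- data[data$oligo == og, ]
    muts <- unique(dd$mutant)
    d <- tibble(x = as.numeric(dd[[xn]]), y = as.numeric(dd[[yn]]),
                mutant_idx = match(dd$mutant, muts))
    counts <- table(d$mutant_idx)
    if (any(counts < 6)) abort(sprintf("oligo %s: every mutant needs >= 6 points.", og))
    if (length(muts) == 1) {
      warn(sprintf("oligo %s has a single mutant; falling back to a per-curve Hill fit.", og))
    }
    r0 <- min(d$y); amp <- max(d$y) - min(d$y)
    lk0 <- vapply(seq_along(muts), function(i) {
      di <- d[d$mutant_idx == i, ]
      half <- tryCatch(stats::approx(di$y, di$x,
                                     xout = min(di$y) + amp / 2,
                                     ties = mean)$y,
                       error = function(e) NA_real_)
      if (is.finite(half) && half > 0) log10(half) else
        stats::median(log10(di$x[di$x > 0]))
    }, numeric(1))
    start <- c(r0 = r0, amplitude = amp, n = 1,
               setNames(lk0, paste0("lk_", seq_along(muts))))
    lower <- c(r0 = -Inf, amplitude = 0, n = 0.2,
               setNames(rep(-12, length(muts)), paste0("lk_", seq_along(muts))))
    upper <- c(r0 = Inf, amplitude = Inf, n = 6,
               setNames(rep(0, length(muts)), paste0("lk_", seq_along(muts))))
    ans <- zf_nls(d, list(start), aniso_fn, lower = lower, upper = upper)
    fit <- new_zf_fit(d, ans$par, aniso_fn,
                      function(dd2) {
                        abort("outlier refitting is not supported for global anisotropy fits.")
                      }, "anisotropy_oligo_fit")
    fits[[og]] <- fit
    ses <- zf_se(fit)
    for (i in seq_along(muts)) {
      lk <- fit$par[[paste0("lk_", i)]]
      k <- 10^lk
      se_k <- ses[[paste0("lk_", i)]] * log(10) * k
      capped <- k > floor_M
      out_rows[[length(out_rows) + 1]] <- tibble(
        oligo = og, mutant = muts[i],
        k_dna_M = if (capped) floor_M else k,
        se = if (capped) NA_real_ else se_k,
        floor_flag = capped,
        hill_n = fit$par[["n"]], se_n = ses[["n"]],
        amplitude = fit$par[["amplitude"]], r0 = fit$par[["r0"]])
    }
  }
  structure(list(kdna = dplyr::bind_rows(out_rows), fits = fits,
                 floor_M = floor_M),
            class = "anisotropy_fit")
}

#' @export
print.anisotropy_fit <- function(x, ...) {
  cat(sprintf("<anisotropy_fit> %d oligos, %d mutant curves (K_DNA floor %.3g M)\n",
              length(x$fits), nrow(x$kdna), x$floor_M))
  print(x$kdna, n = Inf)
  invisible(x)
}

#' K_DNA matrix relative to the wild type
#'
#' Expresses each mutant's DNA affinity relative to the wild type per oligo:
#' relative = K_DNA(WT) / K_DNA(mutant), so values above 1 mean tighter
#' binding than WT. Floor-capped entries only bound the affinity from above,
#' so their relative value carries a "<=" qualifier.
#'
#' @param kdna Tibble as produced in `fit_anisotropy_global()$kdna` (needs
#'   `oligo`, `mutant`, `k_dna_M`, `floor_flag`).
#' @param wt_label Label of the wild-type mutant column (default "WT").
#' @return Tibble with `oligo`, `mutant`, `relative_affinity`, `qualifier`
#'   ("" or "<=").
#' @export
kdna_relative_matrix <- function(kdna, wt_label = "WT") {
  need <- c("oligo", "mutant", "k_dna_M")
  if (!all(need %in% names(kdna))) {
    abort("`kdna` needs columns oligo, mutant, k_dna_M.")
  }
  if (!"floor_flag" %in% names(kdna)) kdna$floor_flag <- FALSE
  wt <- kdna[kdna$mutant == wt_label, c("oligo", "k_dna_M")]
  if (nrow(wt) == 0) abort(sprintf("no '%s' entries found.", wt_label))
  names(wt)[2] <- "k_wt"
  out <- dplyr::left_join(kdna, wt, by = "oligo")
  if (anyNA(out$k_wt)) abort("some oligos lack a wild-type reference.")
  dplyr::transmute(out, .data$oligo, .data$mutant,
                   relative_affinity = .data$k_wt / .data$k_dna_M,
                   qualifier = ifelse(.data$floor_flag, "<=", ""))
}
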