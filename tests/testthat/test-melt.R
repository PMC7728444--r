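# Denaturation melt fitting, pooled m-values, linkage and stability
# regression, and the outlier-rejection rule.

test_that("noiseless melts are recovered exactly by the LEM fit", {
  sim <- gen_melt_panel(n_curves = 1, dg = 6.0, m = 3.0, noise_sd = 0,
                        seed = 1)
  fit <- fit_lem_curve(sim$data)
  td <- tidy(fit)
  est <- setNames(td$estimate, td$term)
  expect_rel_equal(est[["dg"]], 6.0, 1e-6)
  expect_rel_equal(est[["m"]], 3.0, 1e-6)
  expect_rel_equal(est[["a_n"]], 1.0, 1e-6)
  # midpoint identity C_m = dG / m
  expect_equal(est[["c_m"]], est[["dg"]] / est[["m"]], tolerance = 1e-9)
})

test_that("GdnHCl melts fit with the steeper m prior", {
  sim <- gen_melt_panel(n_curves = 1, dg = 6.0, m = 7.0,
                        denaturant = seq(0, 3, length.out = 20),
                        noise_sd = 0, denaturant_kind = "GdnHCl", seed = 1)
  fit <- fit_lem_curve(sim$data, denaturant_kind = "GdnHCl")
  expect_rel_equal(coef(fit)[["m"]], 7.0, 1e-6)
})

test_that("noisy melt fits cover the true stability at the stated rate", {
  hits <- 0; n_rep <- 60
  for (s in seq_len(n_rep)) {
    sim <- gen_melt_panel(n_curves = 1, dg = 6.0, m = 3.0, noise_sd = 0.02,
                          seed = 100 + s)
    fit <- fit_lem_curve(sim$data)
    td <- tidy(fit)
    dg_hat <- td$estimate[td$term == "dg"]
    se <- td$std.error[td$term == "dg"]
    if (abs(dg_hat - 6.0) <= 2 * se) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.85)   # ~95% nominal, binomial slack at n = 60
})

test_that("degenerate melts raise informative errors", {
  flat <- tibble::tibble(denaturant_M = seq(0, 8, length.out = 12),
                         signal = 1 - 0.01 * seq(0, 8, length.out = 12))
  expect_error(fit_lem_curve(flat), "transition")
  short <- gen_melt_panel(noise_sd = 0, seed = 1)$data[1:5, ]
  expect_error(fit_lem_curve(short), "8 points")
})

test_that("m-value pooling averages per denaturant with the right SE", {
  same <- tibble::tibble(m_value = rep(3.1, 5))
  p <- pool_m_values(same)
  expect_equal(p$m_pool, 3.1)
  expect_equal(p$se, 0)
  # sampling arithmetic at the reported pool size
  set.seed(3)
  ms <- stats::rnorm(213, 3.10, 0.12 * sqrt(213))
  p213 <- pool_m_values(tibble::tibble(m_value = ms))
  expect_equal(p213$se, 0.12, tolerance = 0.25)
  expect_equal(p213$n, 213L)
  # urea and GdnHCl pooled separately
  mixed <- tibble::tibble(m_value = c(3.0, 3.2, 7.0, 7.1),
                          denaturant_kind = c("urea", "urea",
                                              "GdnHCl", "GdnHCl"))
  pm <- pool_m_values(mixed)
  expect_equal(sort(pm$m_pool), c(3.1, 7.05))
  expect_error(pool_m_values(tibble::tibble(m_value = numeric())), "pool")
})

test_that("dG from the midpoint uses the pooled m with quadrature SE", {
  expect_equal(dg_from_cm(1.0, 3.10)$dg, 3.10)
  expect_equal(dg_from_cm(2.065, 3.10)$dg, 6.4015, tolerance = 1e-6)
  out <- dg_from_cm(2.0, 3.1, se_cm = 0.05, se_m = 0.12)
  expect_equal(out$se, sqrt((3.1 * 0.05)^2 + (2.0 * 0.12)^2),
               tolerance = 1e-12)
  expect_error(dg_from_cm(-1, 3.1), "positive")
})

test_that("pooled-m stabilities are more precise than per-curve dG", {
  sim <- gen_melt_panel(n_curves = 12, dg = 6.0, m = 3.0, noise_sd = 0.02,
                        seed = 5)
  fits <- fit_melt_curves(sim$data)
  pool <- pool_m_values(fits)
  pooled <- dg_from_cm(fits$c_m, pool$m_pool, fits$se_cm, pool$se)
  expect_lt(mean(pooled$se), mean(fits$se_dg))
})

test_that("linkage profile fitting inverts dg_fold exactly at zero noise", {
  lp <- gen_linkage_profile(noise_sd = 0, seed = 1)
  fit <- fit_linkage_profile(lp$data, k_zn_u = 4.2e-8)
  expect_rel_equal(coef(fit)[["dg_apo"]], lp$truth$dg_apo, 1e-6)
  expect_rel_equal(10^coef(fit)[["log10_k_zn"]], lp$truth$k_zn, 1e-6)
  expect_true(fit$k_zn_identifiable)
})

test_that("noisy linkage profiles recover the generating parameters", {
  lp <- gen_linkage_profile(noise_sd = 0.2, seed = 17)
  fit <- fit_linkage_profile(lp$data, k_zn_u = 4.2e-8)
  td <- tidy(fit)
  dg_hat <- td$estimate[td$term == "dg_apo"]
  expect_lt(abs(dg_hat - lp$truth$dg_apo), 0.3)
  lk_hat <- td$estimate[td$term == "log10_k_zn"]
  expect_lt(abs(lk_hat - log10(lp$truth$k_zn)), 0.5)
  expect_true(all(td$std.error > 0))
})

test_that("mutant linkage signatures separate zinc and stability classes", {
  wt <- wt_dbd_params("linkage")
  znmut <- make_mutant_params(wt, "zn", ddg_apo = 0, k_zn = wt$k_zn * 300)
  stmut <- make_mutant_params(wt, "st", ddg_apo = 2.0)
  z_wide <- 10^seq(-16, -10, length.out = 14)
  f_zn <- fit_linkage_profile(
    tibble::tibble(zn_free_M = z_wide, dg = dg_fold(znmut, z_wide, 283.15)),
    k_zn_u = wt$k_zn_u)
  f_st <- fit_linkage_profile(
    tibble::tibble(zn_free_M = z_wide, dg = dg_fold(stmut, z_wide, 283.15)),
    k_zn_u = wt$k_zn_u)
  # zinc class: same intercept, deflection shifted to higher zinc
  expect_rel_equal(coef(f_zn)[["dg_apo"]], dg_apo(wt, 283.15), 1e-4)
  expect_equal(coef(f_zn)[["log10_k_zn"]] - log10(wt$k_zn), log10(300),
               tolerance = 1e-3)
  # stability class: intercept dropped by 2, deflection unchanged
  expect_rel_equal(coef(f_st)[["dg_apo"]], dg_apo(wt, 283.15) - 2, 1e-4)
  expect_equal(coef(f_st)[["log10_k_zn"]], log10(wt$k_zn), tolerance = 1e-3)
})

test_that("flat linkage profiles flag K_Zn as non-identifiable", {
  # the tyrosine-to-cysteine behaviour: dG never rises in the zinc window
  z <- 10^seq(-16, -12, length.out = 10)
  flat <- tibble::tibble(zn_free_M = z, dg = 4.0 + 0.01 * seq_along(z))
  expect_warning(fit <- fit_linkage_profile(flat, k_zn_u = 4.2e-8),
                 "non-identifiable")
  expect_false(fit$k_zn_identifiable)
  expect_equal(coef(fit)[["dg_apo"]], 4.0, tolerance = 0.2)
})

test_that("stability curves invert the Gibbs-Helmholtz model", {
  ss <- gen_stability_series(noise_sd = 0, seed = 1)
  fit <- fit_stability_curve(ss$data)
  expect_rel_equal(coef(fit)[["dh_m"]], 171, 1e-5)
  expect_rel_equal(coef(fit)[["t_m"]], 300, 1e-6)
  expect_rel_equal(coef(fit)[["dc_p"]], 7.0, 1e-5)
  # fitted T_m is the dG = 0 crossing of the fitted curve
  root <- stats::uniroot(function(tt) {
    p <- coef(fit)
    gibbs_helmholtz_dg(tt, p[["dh_m"]], p[["t_m"]], p[["dc_p"]])
  }, c(290, 320))$root
  expect_equal(root, coef(fit)[["t_m"]], tolerance = 1e-6)
  expect_error(fit_stability_curve(ss$data[1:4, ]), "6 temperatures")
})

test_that("outlier rule leaves clean data untouched", {
  for (s in 1:20) {
    lp <- gen_linkage_profile(noise_sd = 0.2, seed = 400 + s)
    fit <- fit_linkage_profile(lp$data, k_zn_u = 4.2e-8)
    res <- reject_outliers(fit)
    expect_identical(sum(res$data$outlier), 0L)
  }
})

test_that("a single gross outlier is rejected, and exactly that point", {
  lp <- gen_linkage_profile(noise_sd = 0.2, n_outliers = 1, seed = 1003)
  fit <- fit_linkage_profile(lp$data, k_zn_u = 4.2e-8)
  res <- reject_outliers(fit)
  expect_identical(which(res$data$outlier), which(lp$data$outlier_truth))
  # the refit recovers the generating stability more closely
  expect_lt(abs(coef(res$fit)[["dg_apo"]] - lp$truth$dg_apo),
            abs(coef(fit)[["dg_apo"]] - lp$truth$dg_apo))
  expect_true(all(c("round", "row", "deletion_z", "alpha_adj",
                    "decision") %in% names(res$audit)))
})

test_that("two gross outliers are both caught; mild scatter is not", {
  lp2 <- gen_stability_series(noise_sd = 0.3, n_outliers = 2,
                              outlier_sigma = 8, seed = 2004)
  fit2 <- fit_stability_curve(lp2$data)
  res2 <- reject_outliers(fit2)
  expect_identical(which(res2$data$outlier), which(lp2$data$outlier_truth))
  # 1-sigma "outliers" are indistinguishable from noise: nothing rejected
  mild <- gen_stability_series(noise_sd = 0.3, n_outliers = 2,
                               outlier_sigma = 1, seed = 2004)
  resm <- reject_outliers(fit_stability_curve(mild$data))
  expect_identical(sum(resm$data$outlier), 0L)
})
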