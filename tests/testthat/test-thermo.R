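# Four-state linkage model and energy landscapes.

test_that("Gibbs-Helmholtz stability curve matches closed-form values", {
  expect_equal(gibbs_helmholtz_dg(300, 171, 300, 7.0), 0)
  # direct arithmetic evaluation of the formula at 10 and 37 degrees C
  expect_equal(gibbs_helmholtz_dg(283.15, 171, 300, 7.0), 6.228252,
               tolerance = 1e-6)
  expect_equal(gibbs_helmholtz_dg(310.15, 171, 300, 7.0), -6.974099,
               tolerance = 1e-6)
  expect_error(gibbs_helmholtz_dg(-5, 171, 300, 7.0), "positive")
})

test_that("stability is maximal at Ts = Tm exp(-dHm/(dCp Tm))", {
  ts <- 300 * exp(-171 / (7 * 300))
  tgrid <- seq(260, 300, by = 0.01)
  dg <- gibbs_helmholtz_dg(tgrid, 171, 300, 7.0)
  expect_equal(tgrid[which.max(dg)], ts, tolerance = 1e-4)
  # parabola-like: decreasing on both sides of the maximum
  expect_lt(gibbs_helmholtz_dg(ts - 10, 171, 300, 7.0),
            gibbs_helmholtz_dg(ts, 171, 300, 7.0))
  expect_lt(gibbs_helmholtz_dg(ts + 10, 171, 300, 7.0),
            gibbs_helmholtz_dg(ts, 171, 300, 7.0))
})

test_that("folding equilibrium constant follows K = exp(+dG/RT)", {
  expect_equal(kapo_from_dg(0, 283.15), 1)
  expect_equal(kapo_from_dg(6.4, 283.15), 87048.9, tolerance = 1e-4)
  expect_equal(kapo_from_dg(-6.9, 310.15), 1.37386e-5, tolerance = 1e-4)
})

test_that("zinc linkage free energy has the right closed forms and limits", {
  expect_equal(zinc_linkage_dg(1e-15, 0, 283.15), 0)
  expect_equal(zinc_linkage_dg(3e-9, 3e-9, 283.15), -0.390017,
               tolerance = 1e-5)
  # asymptote: slope of -RT per e-fold once zn >> k_d
  rt <- 1.9872e-3 * 283.15
  v1 <- zinc_linkage_dg(1e-15, 1e-9, 283.15)
  v2 <- zinc_linkage_dg(1e-15, exp(1) * 1e-9, 283.15)
  expect_equal(v2 - v1, -rt, tolerance = 1e-5)
  expect_error(zinc_linkage_dg(1e-15, -1, 283.15), "non-negative")
  expect_error(zinc_linkage_dg(-1, 1e-9, 283.15), "> 0")
})

test_that("dg_fold reduces to dg_apo at zero zinc and matches arithmetic", {
  wt <- thermo_params("WT", k_zn = 7.0e-15, k_zn_u = 4.2e-8,
                      dg_apo_ref = 6.4)
  expect_equal(dg_fold(wt, 0, 283.15), 6.4)
  expect_equal(dg_fold(wt, 1e-12, 283.15), 9.195821, tolerance = 1e-6)
})

test_that("dg_fold is monotone in zinc with plateaus at both extremes", {
  wt <- wt_dbd_params("linkage")
  z <- 10^seq(-20, -2, by = 0.1)
  dg <- dg_fold(wt, z, 283.15)
  expect_true(all(diff(dg) >= -1e-12))
  # plateau below K_Zn and above K_Zn,U
  expect_lt(abs(dg_fold(wt, 1e-19, 283.15) - dg_fold(wt, 0, 283.15)), 1e-3)
  expect_lt(dg_fold(wt, 1e-3, 283.15) - dg_fold(wt, 1e-4, 283.15), 0.01)
})

test_that("species fractions normalise, stay in [0,1], and respect limits", {
  wt <- wt_dbd_params()
  fr0 <- species_fractions(wt, 0, 310.15)
  expect_equal(fr0$f_nzn, 0)
  expect_equal(fr0$f_uzn, 0)

  set.seed(42)
  n <- 1e5
  dg <- stats::runif(n, -10, 10)
  z <- 10^stats::runif(n, -18, -4)
  kzn <- 10^stats::runif(n, -16, -10)
  kznu <- kzn * 10^stats::runif(n, 1, 8)
  temp <- stats::runif(n, 270, 320)
  fr <- four_state_fractions(dg, z, kzn, kznu, temp)
  tot <- fr$f_u + fr$f_n + fr$f_nzn + fr$f_uzn
  expect_lt(max(abs(tot - 1)), 1e-9)
  expect_true(all(fr$f_u >= 0 & fr$f_u <= 1))
  expect_true(all(fr$f_nzn >= 0 & fr$f_nzn <= 1))
})

test_that("f_nzn rises monotonically in zinc to its analytic plateau", {
  wt <- wt_dbd_params()
  z <- 10^seq(-16, -2, by = 0.05)
  fr <- species_fractions(wt, z, 310.15)
  expect_true(all(diff(fr$f_nzn) >= -1e-12))
  kapo <- kapo_from_dg(dg_apo(wt, 310.15), 310.15)
  plateau <- (kapo / wt$k_zn) / (kapo / wt$k_zn + 1 / wt$k_zn_u)
  expect_equal(fr$f_nzn[length(z)], plateau, tolerance = 1e-4)
})

test_that("two routes to the folding free energy agree", {
  # exp(dg_fold/RT) must equal (f_n + f_nzn)/(f_u + f_uzn) at any condition
  wt <- wt_dbd_params("linkage")
  for (temp in c(283.15, 298.15, 310.15)) {
    z <- 10^seq(-16, -7, by = 0.5)
    fr <- species_fractions(wt, z, temp)
    lhs <- exp(dg_fold(wt, z, temp) / (1.9872e-3 * temp))
    rhs <- (fr$f_n + fr$f_nzn) / (fr$f_u + fr$f_uzn)
    expect_lt(max(abs(lhs / rhs - 1)), 1e-9)
  }
})

test_that("holo stability transform has the right closed form and domain", {
  expect_equal(dg_holo_theory(0.5, 310.15), 0)
  expect_equal(dg_holo_theory(0.9905, 310.15), -2.864035, tolerance = 1e-6)
  expect_error(dg_holo_theory(0, 310.15), "strictly between")
  expect_error(dg_holo_theory(1, 310.15), "strictly between")
})

test_that("closed-system solver matches closed-form and bisection oracles", {
  wt <- wt_dbd_params()
  # trivial: no zinc
  cs0 <- solve_closed_system(wt, 310.15, 2.5e-6, 0)
  expect_equal(cs0$f_nzn, 0)
  expect_equal(cs0$zn_free_M, 0)
  # equimolar low-micromolar regime
  cs <- solve_closed_system(wt, 310.15, 2.5e-6, 2.5e-6)
  w_quad <- oracle_closed_system_w(wt, 310.15, 2.5e-6, 2.5e-6)
  w_bis <- oracle_bisect_w(wt, 310.15, 2.5e-6, 2.5e-6)
  expect_rel_equal(cs$zn_free_M, w_quad, 1e-8)
  expect_rel_equal(cs$zn_free_M, w_bis, 1e-8)
  expect_gt(cs$f_nzn, 0.98)
  # random parameter draws
  set.seed(7)
  for (i in 1:25) {
    p <- thermo_params("rnd", k_zn = 10^stats::runif(1, -16, -12),
                       k_zn_u = 10^stats::runif(1, -9, -6),
                       dg_apo_ref = stats::runif(1, -8, 8),
                       t_ref = 298.15)
    pt <- 10^stats::runif(1, -7, -5)
    zt <- 10^stats::runif(1, -7, -5)
    cs_i <- solve_closed_system(p, 298.15, pt, zt)
    expect_rel_equal(cs_i$zn_free_M,
                     oracle_bisect_w(p, 298.15, pt, zt), 1e-8)
    expect_lt(cs_i$resid_rel, 1e-6)
  }
})

test_that("closed system converges to the buffered limit in excess zinc", {
  wt <- wt_dbd_params()
  zt <- 2.5e-6 * 150
  cs <- solve_closed_system(wt, 310.15, 2.5e-6, zt)
  buf <- species_fractions(wt, zt, 310.15)
  expect_lt(abs(cs$f_nzn / buf$f_nzn - 1), 0.01)
})

test_that("mutant parameter construction shifts the landscape correctly", {
  wt <- wt_dbd_params()
  same <- make_mutant_params(wt, "copy", ddg_apo = 0)
  g1 <- landscape_grid(wt, seq(280, 315, 5), seq(-14, -8, 0.5))
  g2 <- landscape_grid(same, seq(280, 315, 5), seq(-14, -8, 0.5))
  expect_equal(g1$f_holo, g2$f_holo)

  # stability-class mutant: surface shifted toward unfolded everywhere
  destab <- make_mutant_params(wt, "stab", ddg_apo = 2.0)
  expect_equal(dg_apo(wt, 310.15) - dg_apo(destab, 310.15), 2.0)
  expect_equal(dg_apo(wt, 283.15) - dg_apo(destab, 283.15), 2.0)
  g3 <- landscape_grid(destab, seq(280, 315, 5), seq(-14, -8, 0.5))
  mid <- g1$f_holo > 1e-6 & g1$f_holo < 1 - 1e-6
  expect_true(all(g3$f_holo[mid] < g1$f_holo[mid]))

  # zinc-class mutant: deflection shifts +3 log units, intercept unchanged
  znmut <- make_mutant_params(wt, "zn", ddg_apo = 0, k_zn = wt$k_zn * 1e3)
  expect_equal(dg_fold(znmut, 0, 283.15), dg_fold(wt, 0, 283.15))
  z <- 1e-13   # K_Zn << z << K_Zn,U for both variants
  expect_equal(dg_fold(znmut, z * 1e3, 283.15), dg_fold(wt, z, 283.15),
               tolerance = 1e-3)
  expect_equal(znmut$k_zn_u, wt$k_zn_u)
})

test_that("landscape grid is monotone in zinc and in warm temperature", {
  wt <- wt_dbd_params()
  temps <- seq(284, 330, by = 2)
  logz <- seq(-16, -7, by = 0.25)
  g <- landscape_grid(wt, temps, logz)
  expect_true(all(g$f_holo >= 0 & g$f_holo <= 1))
  by_t <- split(g$f_holo, g$temperature_K)
  expect_true(all(vapply(by_t, function(r) all(diff(r) >= -1e-12),
                         logical(1))))
  warm <- g[g$temperature_K >= wt$t_m - 20 & g$log10_zn_free_M >= -10, ]
  by_z <- split(warm$f_holo, warm$log10_zn_free_M)
  expect_true(all(vapply(by_z, function(cc) all(diff(cc) <= 1e-12),
                         logical(1))))
  # cold protein is nearly all holo at moderate zinc
  cold <- landscape_grid(wt, c(283.15, 284.15), seq(-12, -8, 1))
  expect_true(all(cold$f_holo > 0.99))
  expect_error(landscape_grid(wt, c(300, 290), c(-10, -9)), "ascending")
})

test_that("thermo_params enforces its invariants", {
  expect_error(thermo_params("x", k_zn = 1e-8, k_zn_u = 1e-15,
                             dg_apo_ref = 5), "tighter")
  expect_error(thermo_params("x", k_zn = -1, k_zn_u = 1e-8, dg_apo_ref = 5),
               "> 0")
  expect_error(thermo_params("x", k_zn = 1e-15, k_zn_u = 1e-8), "Supply")
  wt <- wt_dbd_params()
  expect_equal(wt$dg_apo_ref, gibbs_helmholtz_dg(283.15, 171, 300, 7.0))
})
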