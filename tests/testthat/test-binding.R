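# Direct titrations, FluoZin-3 competition, and global DNA-anisotropy fits.

test_that("single-site fits invert the binding equation exactly", {
  sim <- gen_titration(k_zn = 1.6e-15, noise_sd = 0, seed = 1)
  fit <- fit_single_site(sim$data)
  td <- tidy(fit)
  expect_rel_equal(td$estimate[td$term == "k_d"], 1.6e-15, 1e-6)
  expect_rel_equal(coef(fit)[["f0"]], 1, 1e-6)
  # half-saturation: F(K) - F0 = A/2 on the fitted curve
  pred <- fit$fn(coef(fit), tibble::tibble(x = 1.6e-15))
  expect_equal(pred - coef(fit)[["f0"]], coef(fit)[["amplitude"]] / 2,
               tolerance = 1e-6)
})

test_that("noisy femtomolar titrations recover K_Zn within its spread", {
  ks <- vapply(1:30, function(s) {
    sim <- gen_titration(k_zn = 1.6e-15, noise_sd = 0.01, seed = 200 + s)
    td <- tidy(fit_single_site(sim$data))
    td$estimate[td$term == "k_d"]
  }, numeric(1))
  expect_lt(abs(median(ks) - 1.6e-15), 0.3e-15)
})

test_that("the Hill fit nests the single-site model", {
  sim <- gen_titration(k_zn = 1.6e-15, n = 1, noise_sd = 0, seed = 1)
  hf <- fit_hill(sim$data)
  sf <- fit_single_site(sim$data)
  expect_equal(coef(hf)[["n"]], 1, tolerance = 1e-5)
  expect_rel_equal(10^coef(hf)[["log10_k"]], 10^coef(sf)[["log10_k"]], 1e-5)
  # independent sites on a tetramer read out as n = 1 under noise
  ns <- vapply(1:20, function(s) {
    noisy <- gen_titration(k_zn = 1.6e-15, n = 1, noise_sd = 0.01,
                           seed = 300 + s)
    coef(fit_hill(noisy$data))[["n"]]
  }, numeric(1))
  expect_lt(abs(median(ns) - 1), 0.05)
  # genuinely cooperative data: n = 2 recovered within 2 SE
  coop <- gen_titration(k_zn = 1.6e-15, n = 2, noise_sd = 0.01, seed = 9)
  hf2 <- fit_hill(coop$data)
  td2 <- tidy(hf2)
  expect_lt(abs(coef(hf2)[["n"]] - 2),
            2 * td2$std.error[td2$term == "n"] + 0.02)
})

test_that("competition forward model honours its closed-form anchors", {
  setup <- competition_setup(fz3_total = 30e-9, zn_total = 15e-9,
                             k_fz3 = 15e-9)
  at0 <- simulate_competition(setup, 0, k_protein = 42e-9)
  expect_rel_equal(at0$fz3_zn_M, oracle_fz3_complex(30e-9, 15e-9, 15e-9),
                   1e-9)
  expect_equal(at0$fz3_zn_M, 8.787e-9, tolerance = 1e-3)
  expect_equal(y0_exact(setup), 0.4142136, tolerance = 1e-6)
  # protein excess strips the indicator
  hi <- simulate_competition(setup, 1e-2, k_protein = 42e-9)
  expect_lt(hi$fz3_zn_M / at0$fz3_zn_M, 1e-3)
})

test_that("competition model conserves zinc and indicator everywhere", {
  setup <- competition_setup()
  grid <- 10^seq(-9, -4, length.out = 15)
  sim <- simulate_competition(setup, grid, k_protein = 42e-9)
  bound_p <- grid * sim$zn_free_M / (42e-9 + sim$zn_free_M)
  zn_tot <- sim$zn_free_M + sim$fz3_zn_M + bound_p
  expect_lt(max(abs(zn_tot / setup$zn_total - 1)), 1e-9)
})

test_that("the empirical logistic locates the competition midpoint", {
  setup <- competition_setup()
  sim <- gen_competition(k_protein = 42e-9, noise_sd = 0, seed = 1)
  fit <- fit_ic50(sim$data)
  td <- tidy(fit)
  ic50 <- td$estimate[td$term == "ic50"]
  # IC50 equals x at half amplitude of the fitted logistic
  half_pred <- fit$fn(coef(fit),
                      tibble::tibble(x = coef(fit)[["ic50_log10"]]))
  expect_equal(half_pred, coef(fit)[["amplitude"]] / 2, tolerance = 1e-9)
  expect_true(ic50 > 5e-8 && ic50 < 5e-7)
  expect_lt(coef(fit)[["b"]], 0)   # signal falls with competitor
})

test_that("the Munson-Rodbard correction follows its closed form", {
  setup <- competition_setup(fz3_total = 30e-9, zn_total = 15e-9,
                             k_fz3 = 15e-9)
  # worked arithmetic at y0 = 1: 164.5/3.5 - 5 = 42 nM
  out <- ki_from_ic50(164.5e-9, setup, y0 = 1)
  expect_equal(out$k_i_M, 42e-9, tolerance = 1e-6)
  expect_true(out$valid)
  # nominal convention equals zn_total / k_fz3
  expect_equal(ki_from_ic50(164.5e-9, setup)$y0, 1)
  # y0 = 0 limit reduces to the Cheng-Prusoff form
  cp <- ki_from_ic50(150e-9, setup, y0 = 0)
  expect_equal(cp$k_i_M, 150e-9 / (1 + 30 / 15), tolerance = 1e-9)
  # over-correction is flagged, not silently returned
  expect_warning(bad <- ki_from_ic50(1e-9, setup, y0 = 1), "invalid")
  expect_false(bad$valid)
})

test_that("the competition pipeline recovers the unfolded-site affinity", {
  setup <- competition_setup()
  res <- vapply(1:8, function(s) {
    sim <- gen_competition(k_protein = 42e-9, setup = setup,
                           noise_sd = 0.02, seed = 20 + s)
    fit <- fit_ic50(sim$data)
    c(nominal = ki_from_ic50(fit, setup)$k_i_M,
      exact = ki_from_ic50(fit, setup, y0 = "exact")$k_i_M)
  }, numeric(2))
  # nominal y0 = 1 is the reporting convention; exact y0 corrects the
  # indicator-depletion bias almost completely
  expect_lt(abs(median(res["nominal", ]) / 42e-9 - 1), 0.25)
  expect_lt(abs(median(res["exact", ]) / 42e-9 - 1), 0.1)
})

test_that("global anisotropy fits link shape and recover K_DNA per mutant", {
  sim <- gen_anisotropy_panel(noise_sd = 0.002, seed = 31)
  fit <- fit_anisotropy_global(sim$data)
  kd <- fit$kdna
  truth <- sim$truth$kdna
  merged <- dplyr::left_join(kd, truth, by = c("oligo", "mutant"))
  # shared Hill parameter per oligo, near the generating value of 1
  expect_true(all(abs(kd$hill_n - 1) < 0.1))
  expect_equal(length(unique(kd$hill_n)), length(unique(kd$oligo)))
  # measurable entries recovered; unmeasurable ones capped at the floor
  meas <- merged$k_dna_M.y < 25e-6
  expect_lt(max(abs(log10(merged$k_dna_M.x[meas] / merged$k_dna_M.y[meas]))),
            0.1)
  expect_true(all(merged$floor_flag[!meas]))
  expect_true(all(merged$k_dna_M.x[!meas] == 25e-6))
  # rank order preserved within each oligo
  ranks <- merged |>
    dplyr::group_by(oligo) |>
    dplyr::summarise(ok = all(rank(k_dna_M.x, ties.method = "min") ==
                                rank(pmin(k_dna_M.y, 25e-6),
                                     ties.method = "min")))
  expect_true(all(ranks$ok))
})

test_that("identical generating K_DNA values fit identically within SE", {
  truth <- tidyr::expand_grid(oligo = "RE", mutant = c("a", "b", "c"))
  truth$k_dna_M <- 4e-7
  sim <- gen_anisotropy_panel(kdna_truth = truth, noise_sd = 0.002,
                              seed = 33)
  kd <- fit_anisotropy_global(sim$data)$kdna
  spread <- diff(range(log10(kd$k_dna_M)))
  expect_lt(spread, 0.15)
})

test_that("relative K_DNA matrices normalise to the wild type", {
  kd <- tibble::tibble(oligo = rep(c("A", "B"), each = 3),
                       mutant = rep(c("WT", "gain", "floor"), 2),
                       k_dna_M = c(3e-7, 1e-7, 25e-6, 6e-7, 2e-7, 25e-6),
                       floor_flag = rep(c(FALSE, FALSE, TRUE), 2))
  rel <- kdna_relative_matrix(kd, wt_label = "WT")
  expect_true(all(rel$relative_affinity[rel$mutant == "WT"] == 1))
  expect_equal(rel$relative_affinity[rel$mutant == "gain" & rel$oligo == "A"],
               3)
  expect_true(all(rel$qualifier[rel$mutant == "floor"] == "<="))
  expect_error(kdna_relative_matrix(kd, wt_label = "absent"), "no 'absent'")
})
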