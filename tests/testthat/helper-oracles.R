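# Independent oracles used across test files. These re-derive results by a
# different route than the package code (closed-form quadratics, plain
# bisection, direct arithmetic) so round-trip checks are genuinely two-path.

R_ORACLE <- 1.9872e-3

# Closed-form free zinc for the closed protein/zinc system: with
# a = K_apo/K_Zn, b = 1/K_Zn,U, c = (a+b)/(1+K_apo), the zinc balance is a
# quadratic c w^2 + (1 + cP - cZ) w - Z = 0 with a single positive root.
oracle_closed_system_w <- function(params, temperature, protein_total,
                                   zn_total) {
  dg <- dg_apo(params, temperature)
  kapo <- exp(dg / (R_ORACLE * temperature))
  a <- kapo / params$k_zn
  b <- 1 / params$k_zn_u
  cc <- (a + b) / (1 + kapo)
  A <- cc
  B <- 1 + cc * protein_total - cc * zn_total
  # positive root in the cancellation-safe form (C = -zn_total < 0)
  2 * zn_total / (B + sqrt(B^2 + 4 * A * zn_total))
}

# Plain log-space bisection on the same mass balance (independent of the
# closed form above and of the package's solver internals).
oracle_bisect_w <- function(params, temperature, protein_total, zn_total,
                            iters = 300) {
  dg <- dg_apo(params, temperature)
  kapo <- exp(dg / (R_ORACLE * temperature))
  resid <- function(w) {
    q <- 1 + kapo + kapo * w / params$k_zn + w / params$k_zn_u
    bound <- protein_total * (kapo * w / params$k_zn + w / params$k_zn_u) / q
    w + bound - zn_total
  }
  lo <- -30; hi <- log10(zn_total)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (resid(10^mid) > 0) hi <- mid else lo <- mid
  }
  10^((lo + hi) / 2)
}

# Single-chelator buffered zinc: exact quadratic solution of
# Z = w + L w / (K + w).
oracle_single_chelator_w <- function(k_cond, total, zn_total) {
  B <- k_cond + total - zn_total
  # positive root, cancellation-safe (C = -k_cond * zn_total < 0)
  2 * k_cond * zn_total / (B + sqrt(B^2 + 4 * k_cond * zn_total))
}

# Indicator-zinc complex at zero competitor: 1:1 binding quadratic.
oracle_fz3_complex <- function(fz3_total, zn_total, k_fz3) {
  s <- fz3_total + zn_total + k_fz3
  (s - sqrt(s^2 - 4 * fz3_total * zn_total)) / 2
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual / expected - 1)), rel_tol)
}
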