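test_that("gating sigmoids have the half-activation symmetry and slope sign", {
  p <- botc_params()
  expect_equal(gating_inf(-34, p$theta_m, p$sigma_m), 0.5)
  expect_equal(gating_inf(-48, p$theta_h, p$sigma_h), 0.5)
  # negative slope: activation increases with V; positive slope: decreases
  expect_gt(gating_inf(-30, p$theta_m, p$sigma_m),
            gating_inf(-40, p$theta_m, p$sigma_m))
  expect_lt(gating_inf(-30, p$theta_h, p$sigma_h),
            gating_inf(-40, p$theta_h, p$sigma_h))
  # hand-evaluated sigmoid: V=-44, theta=-40, sigma=-6
  expect_equal(gating_inf(-44, -40, -6), 1 / (1 + exp(2 / 3)),
               tolerance = 1e-12)
  expect_error(gating_inf(-40, -40, 0), "nonzero")
})

test_that("gate time constants peak at theta and follow the cosh form", {
  p <- botc_params()
  expect_equal(tau_gate(-29, p$tau_n, p$theta_n, p$sigma_n), 10)
  expect_equal(tau_gate(-48, p$tau_h, p$theta_h, p$sigma_h), 10000)
  expect_equal(tau_gate(0, 10000, -48, 6), 10000 / cosh(4), tolerance = 1e-12)
  vv <- seq(-80, 20, by = 1)
  expect_true(all(tau_gate(vv, 10, -29, -4) <= 10))
  expect_error(tau_gate(-29, -1, -29, -4), "> 0")
})

test_that("CAN activation is a Hill function with the printed SNIC pair", {
  p <- botc_params()
  expect_equal(f_can(0.74, p$K_CAN, p$n_CAN), 0.5)
  expect_lt(f_can(1e-6, p$K_CAN, p$n_CAN), 1e-4)
  expect_gt(f_can(1e6, p$K_CAN, p$n_CAN), 0.999)
  cc <- seq(0.01, 2, by = 0.01)
  expect_true(all(diff(f_can(cc, p$K_CAN, p$n_CAN)) > 0))
  # the published SNIC calcium level maps to the published conductance
  expect_equal(p$gCAN * f_can(0.02942, p$K_CAN, p$n_CAN), 0.02937,
               tolerance = 2e-4)
  expect_error(f_can(-0.1, 0.74, 0.97), "> 0")
})

test_that("memductance is even in the flux and exact for the printed form", {
  expect_equal(memductance(0, 1, 6e-5), 1)
  expect_equal(memductance(10, 1, 6e-5), 1.018)
  phis <- seq(-30, 30, by = 2.5)
  expect_equal(memductance(phis, 1.3, 2e-4), memductance(-phis, 1.3, 2e-4))
})

test_that("ohmic currents vanish at their reversal potentials", {
  p <- botc_params(Iextz = 7, k1 = 0.3)
  st <- full_state(V = p$VL, n = 0.3, h = 0.4, phi = -10, Ca = 0.1, l = 0.8)
  expect_equal(unname(membrane_currents(st, p)["IL"]), 0)
  st2 <- full_state(V = p$Vsyn_e, n = 0.3, h = 0.4, phi = -10, Ca = 0.1,
                    l = 0.8)
  expect_equal(unname(membrane_currents(st2, p)["Itonic_e"]), 0)
  st3 <- full_state(V = p$VK, n = 0.3, h = 0.4, phi = -10, Ca = 0.1, l = 0.8)
  expect_equal(unname(membrane_currents(st3, p)["IK"]), 0)
  st4 <- full_state(V = p$VNa, n = 0.3, h = 0.4, phi = -10, Ca = 0.1, l = 0.8)
  cur <- membrane_currents(st4, p)
  expect_equal(unname(cur[c("INa", "INaP", "ICAN")]), c(0, 0, 0))
})

test_that("full_rhs balances at the analytic sub-equilibria", {
  p <- botc_params(k2 = 3)
  st <- full_state(V = -60, n = gating_inf(-60, p$theta_n, p$sigma_n),
                   h = 0.4, phi = -20, Ca = 0.4, l = p$K_d / (p$K_d + 0.4))
  d <- full_rhs(st, p)
  expect_equal(unname(d["n"]), 0)        # n at its steady state
  expect_equal(unname(d["phi"]), 0)      # V = k2 * phi
  expect_equal(unname(d["l"]), 0)        # l on the l-nullcline
  expect_error(full_rhs(c(V = NaN, n = 0, h = 0, phi = 0, Ca = 1, l = 0), p),
               "finite")
})

test_that("fast_rhs equals the matching components of full_rhs", {
  p <- botc_params(Iextz = 12, k1 = 0.4)
  sts <- random_states(1000)
  for (i in seq_len(nrow(sts))) {
    st <- unlist(sts[i, ])
    fp <- fast_params(p, st[["h"]], p$gCAN * f_can(st[["Ca"]], p$K_CAN,
                                                   p$n_CAN))
    d_full <- full_rhs(st, p)
    d_fast <- fast_rhs(st[c("V", "n", "phi")], fp)
    expect_equal(d_fast, d_full[c("V", "n", "phi")], tolerance = 1e-14)
  }
})

test_that("calcium subsystem is decoupled from the electrical variables", {
  p <- botc_params()
  base <- ca_rhs(0.3, 0.7, p)
  # ca_rhs has no electrical arguments at all; also check through full_rhs
  for (V in c(-70, -30, 10)) {
    st <- c(V = V, n = 0.9, h = 0.05, phi = 12, Ca = 0.3, l = 0.7)
    expect_equal(full_rhs(st, p)[c("Ca", "l")], base, tolerance = 1e-14)
  }
})

test_that("voltage equation is invariant under flux reversal", {
  p <- botc_params(k1 = 0.7, beta = 2e-4)
  for (phi in c(-18, -5, 9)) {
    a <- full_rhs(c(V = -40, n = 0.2, h = 0.3, phi = phi, Ca = 0.2, l = 0.8), p)
    b <- full_rhs(c(V = -40, n = 0.2, h = 0.3, phi = -phi, Ca = 0.2, l = 0.8), p)
    expect_equal(a[["V"]], b[["V"]], tolerance = 1e-14)
  }
})

test_that("analytic fast Jacobian matches central differences", {
  p <- botc_params(Iextz = 9, k1 = 0.25)
  sts <- random_states(100, seed = 7)
  worst <- 0
  for (i in seq_len(nrow(sts))) {
    st <- unlist(sts[i, c("V", "n", "phi")])
    fp <- fast_params(p, sts$h[i], 0.3)
    Ja <- fast_jacobian(st, fp)
    Jn <- numeric_jacobian(function(x) {
      names(x) <- c("V", "n", "phi")
      fast_rhs(x, fp)
    }, st)
    rel <- max(abs(Ja - Jn)) / max(abs(Ja))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-6)
})

test_that("known Jacobian entries come out exactly", {
  p <- botc_params(k2 = 3)
  fp <- fast_params(p, 0.3, 0.1)
  J <- fast_jacobian(c(V = -40, n = 0.3, phi = -12), fp)
  expect_equal(J["phi", "phi"], -p$k2)
  expect_equal(J["phi", "V"], 1)
  # dl/dt is linear in l with coefficient -A*(K_d + Ca)
  Jca <- numeric_jacobian(function(x) ca_rhs(x[1], x[2], p), c(0.3, 0.7))
  expect_equal(Jca[2, 2], -p$A * (p$K_d + 0.3), tolerance = 1e-6)
})
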