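test_that("fold-curve points carry a zero eigenvalue of the 3-D Jacobian", {
  p <- botc_params()
  fc <- fold_curve(p, h_range = c(0.1, 0.3), n_h = 9)
  fc <- fc[fc$gCANTot > 0, ]
  expect_gt(nrow(fc), 5)
  for (i in seq_len(nrow(fc))) {
    fp <- fast_params(p, fc$h[i], max(fc$gCANTot[i], 0))
    fp$gCANTot <- fc$gCANTot[i]
    st <- c(V = fc$V[i], n = gating_inf(fc$V[i], p$theta_n, p$sigma_n),
            phi = fc$V[i] / p$k2)
    ev <- eigen(fast_jacobian(st, fp), only.values = TRUE)$values
    expect_lt(min(abs(ev)), 1e-6)
  }
})

test_that("Hopf-curve points have a pure imaginary pair", {
  p <- botc_params()
  hc <- hopf_curve(p, h_range = c(0.1, 0.3), n_h = 5)
  expect_gt(nrow(hc), 3)
  for (i in seq_len(nrow(hc))) {
    fp <- fast_params(p, hc$h[i], max(hc$gCANTot[i], 0))
    fp$gCANTot <- hc$gCANTot[i]
    st <- c(V = hc$V[i], n = gating_inf(hc$V[i], p$theta_n, p$sigma_n),
            phi = hc$V[i] / p$k2)
    ev <- eigen(fast_jacobian(st, fp), only.values = TRUE)$values
    cp <- ev[abs(Im(ev)) > 1e-9]
    expect_gt(length(cp), 0)
    expect_lt(max(abs(Re(cp))), 1e-8)
  }
})

test_that("the slow trajectory crosses the fold curve when bursting with
           low quiescence, and an equilibrium projection crosses nothing", {
  p <- botc_params()
  fc <- fold_curve(p, h_range = c(0.2, 0.35), n_h = 31)
  proj <- project_trajectory(baseline_traj(), p)
  cr <- curve_crossings(fc[fc$label == "F1", ], proj)
  expect_gt(nrow(cr), 0)
  # a constant (equilibrium) projection never crosses
  const <- data.frame(t = 0:100, gCANTot = 0.05, h = 0.28)
  expect_equal(nrow(curve_crossings(fc, const)), 0)
})

test_that("induction gain shifts the lower branch left, preserving folds", {
  sh <- scurve_shift(c(0, 0.5, 1, 1.5), h_frozen = 0.2834)
  expect_true(all(sh$n_folds == 2))
  # the closed-form curve at a lower-branch voltage moves to smaller
  # conductance as k1 grows
  p <- botc_params()
  g60 <- vapply(c(0, 0.5, 1, 1.5), function(k1) {
    prebotc:::.gcan_of_V(-60, botc_params(k1 = k1), 0.2834)
  }, numeric(1))
  expect_true(all(diff(g60) < 0))
  # k1 = 0 reproduces the unstimulated curve exactly
  eq0 <- equilibrium_curve(botc_params(k1 = 0), 0.2834)
  eqb <- equilibrium_curve(p, 0.2834)
  expect_equal(eq0$gCANTot, eqb$gCANTot, tolerance = 1e-14)
})

test_that("two-parameter termination contour agrees with the 1-parameter
           diagram at the baseline gate value", {
  p <- botc_params()
  hom <- homoclinic_contour(p, h_range = c(0.2834, 0.2834), n_h = 1)
  expect_equal(nrow(hom), 1)
  d <- baseline_diagram()
  expect_equal(hom$gCANTot, d$termination$gCANTot, tolerance = 1e-3)
  expect_equal(hom$type, "hc")
  empty <- homoclinic_contour(p, h_range = c(0.5, 0.4), n_h = 0)
  expect_equal(nrow(empty), 0)
})
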