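test_that("gate-rate maxima follow the cosh form on the voltage window", {
  p <- botc_params()
  Th <- gate_rate_max(p, "h")
  # cosh argument is monotone on [-60, 0] for the h gate: max at V = 0
  expect_equal(Th, cosh(4) / 10000, tolerance = 1e-10)
  # dense-grid brute force agrees
  vv <- seq(-60, 0, length.out = 2e5)
  expect_equal(Th, max(1 / tau_gate(vv, p$tau_h, p$theta_h, p$sigma_h)),
               tolerance = 1e-9)
  # near-flat time constant (huge slope surrogate): rate -> 1/tau_max
  pf <- botc_params(sigma_n = 1e6)
  expect_equal(gate_rate_max(pf, "n"), 1 / pf$tau_n, tolerance = 1e-9)
})

test_that("calcium gain G_c matches its right-endpoint closed form", {
  p <- botc_params()
  Gc <- compute_Gc(p)
  G1 <- p$IP3 * 1 / ((p$IP3 + p$K_I) * (1 + p$K_a))
  expect_equal(Gc, G1^3, tolerance = 1e-12)   # G increasing => max at Ca = 1
  expect_equal(round(Gc, 2), 0.06)
  expect_equal(compute_Gc(p, Ca_range = c(0, 0)), 0)
})

test_that("SERCA scale G_S peaks at K_SERCA with value V_SERCA/(2 K_SERCA)", {
  p <- botc_params()
  expect_equal(compute_Gs(p), p$V_SERCA / (2 * p$K_SERCA), tolerance = 1e-9)
  expect_equal(compute_Gs(p), 1000, tolerance = 1e-6)
})

test_that("flux scale P_max is the max of its three candidates", {
  p <- botc_params()
  expect_equal(compute_Pmax(p, Gc = 0.06, Gs = 1000), 1860)
  expect_equal(compute_Pmax(p, 0, 0), max(p$L_IP3, 0))
  expect_equal(compute_Pmax(p, 0, 5000), 5000)
})

test_that("rate coefficients reproduce the published arithmetic", {
  ts <- timescale_report()
  expect_equal(unname(ts$R["v"]), 0.42)
  expect_equal(unname(ts$R["n"]), 1 / 1.3, tolerance = 1e-10)
  expect_equal(unname(ts$R["h"]), 400)
  expect_equal(unname(ts$R["phi"]), 1)
  expect_equal(unname(ts$R["Ca"]), 0.185 / (1860 * 2.5e-5), tolerance = 1e-10)
  expect_equal(unname(ts$R["l"]), 200)
  expect_equal(ts$Pmax, 1860)
})

test_that("variables classify as fast / slow / super-slow", {
  ts <- timescale_report()
  expect_equal(unname(classify_variables(ts)[c("v", "n", "phi")]),
               rep("fast", 3))
  expect_equal(unname(classify_variables(ts)["Ca"]), "slow")
  expect_equal(unname(classify_variables(ts)[c("h", "l")]),
               rep("superslow", 2))
  # the computed convention gives the same verdict
  tc <- timescale_report(convention = "computed")
  expect_equal(tc$classification, ts$classification)
})

test_that("decade classification rounds half away from zero", {
  expect_equal(timescale_class(1), "fast")
  expect_equal(timescale_class(0.42), "fast")
  expect_equal(timescale_class(31.7), "superslow")  # log10 = 1.50... -> 2
  expect_equal(timescale_class(31.6), "slow")       # log10 = 1.4997 -> 1
  expect_equal(timescale_class(400), "superslow")
  expect_equal(timescale_class(3.98), "slow")
})
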