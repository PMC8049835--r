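test_that("parameter defaults match the published table and validate", {
  p <- botc_params()
  expect_equal(p$C, 21)
  expect_equal(p$gNa, 10)
  expect_equal(p$tau_h, 10000)
  expect_equal(p$K_SERCA, 0.2)
  expect_equal(p$V_SERCA, 400)
  expect_equal(p$K_Ca, 2.5e-5)
  expect_error(botc_params(gNa = -1), ">= 0")
  expect_error(botc_params(sigma = 1.5), "sigma")
  expect_error(botc_params(nonsense = 1), "unknown")
})

test_that("scenario catalogue covers every studied condition uniquely", {
  sc <- reference_scenarios()
  expect_gte(length(sc), 13)
  expect_false(any(duplicated(names(sc))))
  expect_equal(sc$current_30$params$Iextz, 30)
  expect_equal(sc$current_30$params$k1, 0.1)
  expect_equal(sc$current_30$h_preset, 0.0986)
  expect_equal(sc$induction_1.5$params$k1, 1.5)
  expect_equal(sc$induction_1.5$params$Iextz, 0)
  expect_equal(unname(h_presets()["baseline"]), 0.2834)
  expect_equal(sc$sweep_k1$sweep$param, "k1")
})

test_that("toy fixtures have their constructed bifurcations", {
  toy <- toy_scenarios()
  expect_equal(toy$cubic$folds_V, c(-1, 1))
  # Hopf normal form: eigenvalues mu +- i at the origin
  f <- toy$hopf_normal_form$rhs(mu = 0.3)
  J <- numeric_jacobian(f, c(0, 0, 0))
  ev <- eigen(J, only.values = TRUE)$values
  cp <- ev[abs(Im(ev)) > 1e-9]
  expect_equal(max(Re(cp)), 0.3, tolerance = 1e-5)
  # subcritical construction: positive cubic coefficient grows the radius
  g <- toy$hopf_normal_form$rhs(mu = -0.01, lyap_sign = +1)
  r0 <- c(0.5, 0, 0)
  expect_gt(sum(g(r0) * r0), 0)   # radial growth outside the unstable cycle
})

test_that("parameter configs round-trip through YAML and JSON", {
  p <- botc_params(Iextz = 30, k1 = 0.1)
  fy <- tempfile(fileext = ".yaml")
  fj <- tempfile(fileext = ".json")
  write_params(p, fy)
  write_params(p, fj)
  expect_equal(unclass(read_params(fy)), unclass(p), tolerance = 1e-12)
  expect_equal(unclass(read_params(fj)), unclass(p), tolerance = 1e-12)
  expect_error(read_params(tempfile(fileext = ".txt")), "unsupported")
})

test_that("the bundled reference config reproduces the defaults", {
  cfgfile <- system.file("extdata", "table1.yaml", package = "prebotc")
  expect_true(nzchar(cfgfile))
  expect_equal(unclass(read_params(cfgfile)), unclass(botc_params()),
               tolerance = 1e-12)
})

test_that("trajectories round-trip through CSV with metadata", {
  tr <- simulate_full(sim_config(botc_params(), t_end = 1200,
                                 transient = 1000, dt_out = 1))
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unclass(attr(back, "params")), unclass(botc_params()),
               tolerance = 1e-12)
})
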