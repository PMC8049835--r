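test_that("closed-form equilibrium curve zeroes the fast vector field", {
  p <- botc_params(Iextz = 5, k1 = 0.1)
  eq <- equilibrium_curve(p, 0.2375, V_grid = seq(-70, 0, by = 0.5))
  worst <- 0
  for (i in seq(1, nrow(eq), by = 7)) {
    fp <- fast_params(p, 0.2375, max(eq$gCANTot[i], 0))
    fp$gCANTot <- eq$gCANTot[i]
    res <- fast_rhs(c(V = eq$V[i], n = eq$n[i], phi = eq$phi[i]), fp)
    worst <- max(worst, max(abs(res)))
  }
  expect_lt(worst, 1e-10)
})

test_that("pseudo-arclength continuation reproduces the closed form", {
  set.seed(11)
  worst <- 0
  for (k in 1:4) {
    p <- botc_params(Iextz = stats::runif(1, -2, 30),
                     k1 = stats::runif(1, 0, 0.5))
    h <- stats::runif(1, 0.05, 0.3)
    path <- continue_equilibria(p, h, V_start = -65, ds = 0.5,
                                n_steps = 300)
    expect_gt(nrow(path), 50)
    dg <- abs(path$gCANTot - prebotc:::.gcan_of_V(path$V, p, h))
    worst <- max(worst, max(dg))
  }
  expect_lt(worst, 1e-8)
})

test_that("folds carry a zero eigenvalue and stability changes only at
           detected bifurcations", {
  d <- baseline_diagram()
  expect_true(all(d$folds$lambda_min < 1e-6))
  eq <- d$equilibria
  # walk the curve: the stability class may switch only near a fold or
  # Hopf voltage
  marks <- sort(c(d$folds$V, d$hopf$V))
  cls <- ifelse(eq$class %in% c("stable_node", "stable_focus"),
                "stable", "unstable")
  switches <- eq$V[which(cls[-1] != cls[-length(cls)])]
  for (s in switches) expect_lt(min(abs(s - marks)), 0.1)
})

test_that("the upper-branch Hopf is subcritical with a pure imaginary pair", {
  p <- botc_params()
  eq <- equilibrium_curve(p, 0.2834)
  hp <- find_hopf(eq)
  expect_gte(nrow(hp), 1)
  top <- hp[which.max(hp$V), ]
  expect_lt(abs(top$re), 1e-8)
  expect_gt(top$im, 0)
  expect_equal(top$criticality, "subcritical")
})

test_that("toy cubic fold parametrization is located exactly", {
  toy <- toy_scenarios()$cubic
  # root-find the derivative of g(V) = V^3 - 3V on a grid, as the fold
  # finder does for the model's closed form
  vv <- seq(-2, 2, length.out = 400)  # grid avoids landing on the roots
  dg <- 3 * vv^2 - 3
  sc <- which(dg[-1] * dg[-length(dg)] < 0)
  roots <- vapply(sc, function(i)
    stats::uniroot(function(V) 3 * V^2 - 3, c(vv[i], vv[i + 1]),
                   tol = 1e-12)$root, numeric(1))
  expect_equal(sort(roots), toy$folds_V, tolerance = 1e-8)
})

test_that("Newton shooting refines a cycle and its trivial multiplier", {
  p <- botc_params()
  fp <- fast_params(p, 0.2834, 0.20)
  m <- measure_cycle(fp, t_max = 2000)
  expect_true(m$has_cycle)
  rc <- refine_cycle(fp, m$y_end, m$period)
  expect_true(rc$converged)
  expect_lt(rc$residual, 1e-9)
  expect_equal(rc$T, m$period, tolerance = 1e-3)
  triv <- rc$multipliers[which.min(Mod(rc$multipliers - 1))]
  expect_lt(Mod(triv - 1), 1e-3)
})

test_that("unstable cycles continue away from the subcritical Hopf", {
  p <- botc_params()
  eq <- equilibrium_curve(p, 0.2834)
  hp <- find_hopf(eq, probe = FALSE)
  hp <- hp[which.max(hp$V), ]
  br <- continue_cycles_from_hopf(p, 0.2834, hp, dg0 = 5e-4, n_steps = 12)
  expect_gt(nrow(br), 5)
  expect_true(all(br$converged))
  # born unstable: a nontrivial multiplier outside the unit circle
  expect_true(all(br$mult1 > 1))
  # period near the Hopf frequency
  expect_equal(br$period[1], 2 * pi / hp$im, tolerance = 0.1)
})

test_that("cycle termination classes are definitional", {
  folds <- data.frame(type = "fold", label = c("F1", "F2"),
                      gCANTot = c(0.2, 0.03), V = c(-44, -50),
                      lambda_min = c(0, 0))
  expect_equal(classify_cycle_termination(0.0301, folds)$type, "snic")
  expect_equal(classify_cycle_termination(0.12, folds)$type, "hc")
  none <- folds[0, ]
  expect_equal(classify_cycle_termination(0.1, none)$type, "hc")
})

test_that("period diverges monotonically toward the SNIC", {
  d <- snic_diagram()
  cyc <- d$cycles
  low <- cyc[order(cyc$gCANTot), ]
  low <- low[low$gCANTot < d$hopf$gCANTot / 2, ]
  expect_gt(nrow(low), 4)
  # periods increase as gCANTot decreases toward the termination
  expect_true(all(diff(low$period[1:5]) < 0))
  expect_gt(max(cyc$period), 10 * min(cyc$period))
})
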