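test_that("identical configurations give identical trajectories", {
  cfg <- sim_config(botc_params(), t_end = 3000, transient = 1000,
                    dt_out = 0.5)
  a <- simulate_full(cfg)
  b <- simulate_full(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("state invariants hold along the bursting attractor", {
  tr <- baseline_traj()
  eps <- 1e-6
  expect_true(all(tr$n >= -eps & tr$n <= 1 + eps))
  expect_true(all(tr$h >= -eps & tr$h <= 1 + eps))
  expect_true(all(tr$l >= -eps & tr$l <= 1 + eps))
  expect_true(all(tr$Ca > 0))
  expect_true(all(is.finite(as.matrix(tr))))
  expect_true(all(diff(tr$t) > 0))
})

test_that("the full solution's calcium components match the standalone
           subsystem integration", {
  tr <- baseline_traj()
  sub <- simulate_ca(attr(tr, "params"),
                     initial = c(Ca = tr$Ca[1], l = tr$l[1]),
                     t_end = 5000, dt_out = 0.1)
  idx <- seq_len(nrow(sub))
  expect_lt(max(abs(sub$Ca - tr$Ca[idx])), 1e-6)
  expect_lt(max(abs(sub$l - tr$l[idx])), 1e-6)
})

test_that("fast subsystem relaxes to the flux balance at equilibria", {
  p <- botc_params()
  # far left of the spiking window: lower stable node
  fp <- fast_params(p, 0.2834, 0.01)
  tr <- simulate_fast(fp, t_end = 4000, dt_out = 1)
  tail <- tr[tr$t > 3500, ]
  expect_lt(diff(range(tail$V)), 1e-4)            # settled
  expect_equal(tail$phi[nrow(tail)], tail$V[nrow(tail)] / p$k2,
               tolerance = 1e-5)
  # above the subcritical Hopf: stable upper focus
  fp2 <- fast_params(p, 0.2834, 0.5)
  tr2 <- simulate_fast(fp2, initial = c(V = -20, n = 0.5, phi = -7),
                       t_end = 4000, dt_out = 1)
  tail2 <- tr2[tr2$t > 3500, ]
  expect_lt(diff(range(tail2$V)), 1e-3)
  expect_gt(tail2$V[nrow(tail2)], -30)            # depolarized focus
})

test_that("average_h reproduces a constant and needs full cycles", {
  syn <- synthetic_burst()
  syn$h <- rep(0.375, nrow(syn))
  expect_equal(average_h(syn), 0.375, tolerance = 1e-12)
  short <- syn[syn$t < 1500, ]
  expect_error(average_h(short), "burst cycle")
})

test_that("halving solver tolerances leaves the attractor unchanged", {
  p <- botc_params()
  cfg1 <- sim_config(p, t_end = 26000, transient = 20000, dt_out = 0.1)
  cfg2 <- sim_config(p, t_end = 26000, transient = 20000, dt_out = 0.1,
                     rtol = 5e-9, atol = 5e-11)
  a <- simulate_full(cfg1)
  b <- simulate_full(cfg2)
  # compare voltage along matched times over one burst period after
  # aligning to the first burst onset of each run
  sa <- detect_spikes(a)$peak_times
  sb <- detect_spikes(b)$peak_times
  expect_lt(abs(length(sa) - length(sb)), 3)
  expect_lt(abs(sa[1] - sb[1]), 25)
})
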