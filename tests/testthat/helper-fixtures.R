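# Shared fixtures, computed lazily and cached for the whole test session.
# Everything is generated by the package itself; no stored data.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# baseline full-system trajectory (no stimulation), post-transient window
baseline_traj <- function() {
  fixture("baseline_traj", function() {
    simulate_full(sim_config(botc_params(), t_end = 50000,
                             transient = 20000, dt_out = 0.1))
  })
}

# matched fast-slow diagram at the baseline frozen gate
baseline_diagram <- function() {
  fixture("baseline_diagram", function() {
    fastslow_diagram(botc_params(), 0.2834)
  })
}

# SNIC condition: Iextz = 30, k1 = 0.1, h = 0.0986
snic_diagram <- function() {
  fixture("snic_diagram", function() {
    fastslow_diagram(botc_params(Iextz = 30, k1 = 0.1), 0.0986)
  })
}

# deterministic pseudo-random full states within the physiological domain
random_states <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(V = stats::runif(n, -70, 10),
             n = stats::runif(n, 0, 1),
             h = stats::runif(n, 0, 1),
             phi = stats::runif(n, -25, 5),
             Ca = stats::runif(n, 0.01, 1.2),
             l = stats::runif(n, 0, 1))
}

# synthetic bursting voltage trace with a symmetric spike envelope; each
# burst ends at a spike trough so no spurious edge maximum appears
synthetic_burst <- function(dt = 0.1) {
  tq <- seq(0, 1005 - dt, by = dt)              # quiescent stage
  ts <- seq(0, 995 - dt, by = dt)               # spiking stage (ends at trough)
  env <- 30 - 25 * sin(pi * ts / 995)           # symmetric envelope dip
  vq <- rep(-60, length(tq))
  vs <- -30 + env * sin(2 * pi * ts / 20)       # 20 ms spike period
  v <- c(vq, vs, vq, vs, vq, vs, vq)
  t <- seq_along(v) * dt - dt
  structure(data.frame(t = t, V = v), class = c("prebotc_traj", "data.frame"))
}
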