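# prebotc

Fast-slow dynamical analysis of a memristive pre-Bötzinger complex (pre-BötC)
neuron model.

## The scientific problem

Pacemaker neurons of the pre-BötC, the brainstem kernel of the inspiratory
respiratory rhythm, burst: their membrane potential alternates between a
quiescent phase and a volley of spikes. This package implements a
conductance-based model of such a neuron — a Butera-type somatic membrane
with persistent-sodium (NaP) and calcium-activated nonspecific cation (CAN)
currents, driven by a Park–Rubin IP3/endoplasmic-reticulum calcium
oscillator — extended with electromagnetic stimulation: a direct current
*I*<sub>extz</sub> and an induced current through a flux-controlled
memristor,

```
C dV/dt = −I_Na − I_K − I_L − I_NaP − I_tonic-e − I_CAN + I_extz − k1·V·ρ(φ)
ρ(φ)    = α + 3βφ²,      dφ/dt = V − k2·φ
```

with `I_CAN = g_CAN · f([Ca]) · (V − V_Na)` and Hill activation
`f([Ca]) = 1/(1 + (K_CAN/[Ca])^n_CAN)`. The package is written for
computational neuroscientists who want to reproduce, probe, or extend the
multi-timescale analysis of this model:

* **`timescale_report()`** — nondimensionalization: scale constants, the six
  rate coefficients, and the fast / slow / super-slow classification of
  (V, n, φ / [Ca] / h, l).
* **`simulate_full()` / `simulate_fast()` / `simulate_ca()`** — stiff
  integration (deSolve/lsoda over compiled C right-hand sides) of the 6-D
  system and its subsystems.
* **`detect_spikes()`, `spike_isi()`, `segment_phases()`,
  `classify_pattern()`, `pattern_sweep()`, `locate_transition()`** —
  spike/ISI metrics, burst-phase segmentation (quiescence → decaying spikes
  → small-amplitude passage → regrowing spikes), and regime-threshold
  sweeps over `Iextz`, `k1`, `α`, `β`.
* **`equilibrium_curve()`, `find_folds()`, `find_hopf()`,
  `cycle_branch()`, `refine_cycle()`, `fastslow_diagram()`,
  `label_bursting()`** — one-parameter bifurcation analysis of the
  (V, n, φ) fast subsystem in the effective CAN conductance
  `g_CANTot = g_CAN·f([Ca])` at frozen h: the S-shaped equilibrium curve
  (closed form), folds F1/F2, subcritical Hopf, limit-cycle branch with
  fold-of-cycles (LPC), homoclinic (HC) or SNIC termination, and
  Izhikevich-style burst labels.
* **`fold_curve()`, `hopf_curve()`, `lpc_curve()`, `homoclinic_contour()`,
  `curve_crossings()`** — two-parameter curves in the (g_CANTot, h) plane
  with slow-trajectory crossing diagnostics.
* **`ca_nullclines()`, `ca_orbit()`, `gcan_to_ca()`,
  `ip3_activity_scan()`** — the autonomous ([Ca], l) relaxation oscillator
  that paces the burst.

## Worked example

```r
library(prebotc)

p  <- botc_params()                       # published reference parameters
tr <- simulate_full(sim_config(p))        # 40 s attractor after 20 s transient

classify_pattern(tr)
#> [1] "bursting_low_quiescence"

hbar <- average_h(tr)                     # burst-averaged slow gate
hbar
#> [1] 0.292422

d <- fastslow_diagram(p, h_frozen = 0.2834)
d
#> <prebotc_fsdiag> h = 0.2834
#>   folds: F1 at g=0.19936, F2 at g=-1.31120
#>   subH at g = 0.22857  V = -24.308
#>   LPC at g = 0.30653
#>   cycle termination: hc at g = 0.17639 (nearest fold F1 dg = 0.023 )

label_bursting(d, tr)
#> [1] "subHopf/homoclinic via fold/homoclinic"
```

Reading: the neuron bursts with a low-potential quiescent phase; the fast
subsystem has an S-shaped equilibrium curve whose lower knee (F1, at
effective CAN conductance 0.199 nS) launches the burst, a subcritical Hopf
(subH) at 0.229 nS on the upper branch, a fold of limit cycles at 0.307 nS,
and a spiking branch that dies in a homoclinic bifurcation at 0.176 nS —
the hysteresis loop that classifies this burster. At stronger stimulation
(`Iextz = 30, k1 = 0.1`, analyzed at its own burst-averaged h = 0.0986) the
same machinery finds the spiking branch terminating in a saddle-node on an
invariant circle at g_CANTot ≈ 0.0294 nS, coincident with the lower fold.

A thin command-line wrapper over these functions is installed at
`inst/cli/prebotc-cli.R` (subcommands: simulate, timescales, bifurcate1d,
bifurcate2d, ca-subsystem, isi-sweep, scenarios).

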