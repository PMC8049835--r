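---
title: "Fast-slow analysis of the memristive pre-BotC burster: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast-slow analysis of the memristive pre-BotC burster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prebotc)
```

## The model

`prebotc` implements a conductance-based model of a pre-Botzinger complex
(pre-BotC) inspiratory pacemaker neuron, the brainstem cell type that
paces the respiratory rhythm.  The electrical side is a Butera-type
single-compartment membrane with fast sodium, delayed-rectifier potassium,
leak, persistent sodium (NaP), and tonic excitatory drive currents, plus a
calcium-activated nonspecific cation (CAN) current

$$I_{\mathrm{CAN}} = g_{\mathrm{CAN}}\, f([\mathrm{Ca}])\,(V - V_{\mathrm{Na}}),
\qquad f([\mathrm{Ca}]) = \frac{1}{1 + (K_{\mathrm{CAN}}/[\mathrm{Ca}])^{n_{\mathrm{CAN}}}},$$

and two electromagnetic stimulation terms: a direct current
$I_{\mathrm{extz}}$ and an induced current $k_1 V \rho(\varphi)$ through a
flux-controlled memristor with memductance
$\rho(\varphi)=\alpha + 3\beta\varphi^2$; the flux obeys
$\dot\varphi = V - k_2\varphi$.  Calcium is governed by the Park-Rubin
IP3-receptor/ER module: an $({[\mathrm{Ca}]}, l)$ pair where $l$ is the
fraction of non-inactivated IP3 channels, with IP3-gated ER release, a
SERCA pump $J_{\mathrm{out}} = V_{\mathrm{SERCA}}[\mathrm{Ca}]^2 /
(K_{\mathrm{SERCA}}^2+[\mathrm{Ca}]^2)$, and closed total calcium.  The
calcium pair drives the membrane through $I_{\mathrm{CAN}}$ but receives no
feedback: it is an autonomous slow oscillator pacing the burst.

The gating and time-constant expressions follow the Butera convention,

$$x_\infty(V) = \frac{1}{1+e^{(V-\theta_x)/\sigma_x}}, \qquad
\tau_x(V) = \frac{\bar\tau_x}{\cosh\!\big((V-\theta_x)/2\sigma_x\big)},$$

the forms used by the models this one extends.  All printed constants are
used as given, mutually consistent in the nS/mV/ms convention (the
capacitance 21 divides the current sum directly).  Two derived checks
support this reading: the SERCA rate coefficient
$V_{\mathrm{SERCA}}[\mathrm{Ca}]/(K_{\mathrm{SERCA}}^2+[\mathrm{Ca}]^2)$
peaks at exactly $V_{\mathrm{SERCA}}/2K_{\mathrm{SERCA}} = 1000$, and the
burst-averaged NaP inactivation gate reproduces the reference values at
three independent stimulation conditions to three decimals (see the test
suite).

## Timescales

`timescale_report()` nondimensionalizes the system with voltage/flux scale
100 mV, calcium scale 1 uM, and time scale 1 ms.  The rate coefficients

$$R_v = \frac{C}{Q_t\,g_{\max}},\quad R_n = \frac{1}{Q_t T_n},\quad
R_h = \frac{1}{Q_t T_h},\quad R_\varphi = \frac{1}{Q_t},\quad
R_c = \frac{\sigma}{Q_t P_{\max} K_{\mathrm{Ca}}},\quad
R_l = \frac{1}{Q_t Q_c A}$$

measure how slowly each variable moves.  Each is mapped to its nearest
decade (rounding half away from zero on the log scale) and the three-way
verdict is: decade 0 or below, fast; decade 1, slow; decade 2 or above,
super-slow.  With the reference constants this classifies $(V, n, \varphi)$
as fast, $[\mathrm{Ca}]$ as slow, and $(h, l)$ as super-slow — a genuine
three-timescale system.  Two conventions are carried side by side: the
`computed` one evaluates $T_n$, $T_h$, $G_c$, $G_S$ from the model
functions; the `printed` one (default) uses the published constants
($T_n = 1.3$, $T_h = 0.0025$ per ms, $G_S = 1000$, $G_c$ to two decimals)
so that the published arithmetic ($P_{\max}=1860$, $R_c \approx 3.98$ ms)
is reproduced exactly.  The computed maximum of $1/\tau_n$ on
$[-60, 0]$ mV is 2.41 rather than the printed 1.3 per ms (a figure-read
constant); the discrepancy is surfaced in the report rather than hidden,
and the classification is identical under both conventions.  The normalizer $g_{\max}$ defaults to
50, the top of the explored current range, which dominates every
conductance.

## Simulation

Integration uses `deSolve::lsoda` with right-hand sides compiled from C
(`src/model.c`); defaults are `rtol = 1e-8`, `atol = 1e-10`, output
sampling 0.05 ms (about 20 samples per ms, enough to resolve spike peaks),
and a 20 s discarded transient from a fixed initial state inside the
bursting basin.  The model is deterministic: identical configurations give
identical trajectories.  Halving the tolerances changes spike counts by at
most one and matched interspike intervals by under 2% (asserted in the
suite).

## Spike metrics and regime classification

Spikes are local voltage maxima above -35 mV with at least 1 mV
prominence, with quadratically interpolated peak times.  The 1 mV
prominence (rather than a larger cutoff) keeps the decaying-envelope spike
run continuous, as in the published interspike-interval (ISI) diagrams; in
this implementation the oscillation around the depolarized focus decays
below any resolvable amplitude during the mid-burst passage, so that
passage presents as a spike-free depolarized span.

A burst cycle splits into four phases: (1) the low-potential quiescent
stage, (2) the decaying-amplitude spike run, (3) the small-amplitude
passage near the depolarized focus, (4) the regrowing spike run.  Pattern
classification is by spike-free-gap anatomy: a gap of at least 200 ms
whose mean voltage lies below -35 mV is a low-potential quiescent phase; a
gap of at least 300 ms with mean voltage above -35 mV is a depolarized
plateau.  The -35 mV ceiling was calibrated on the attractors themselves:
the low rest rises with stimulation (from about -54 mV unstimulated to
about -42 mV just before it disappears) while the depolarized passage sits
near -24 mV at every condition, so -35 mV separates the two clusters with
a wide margin.  Labels: low gap present, `bursting_low_quiescence`;
plateau but no low gap, `bursting_high_quiescence`; spikes without long
gaps, `continuous_spiking`; no spikes, `quiescent`.

Under these conventions the loss of the low-potential quiescent phase
lands exactly on the reference thresholds (direct current 33.5, induction
gain 0.88).  The onset of the depolarized plateau is
convention-dependent: because the mid-burst oscillation decays below
resolvable amplitude early, the 300 ms plateau criterion is met from about
$I_{\mathrm{extz}} \approx 41$ and $k_1 \approx 1.2$ onward, several units
before the reference figure-read onsets (47.7 and 1.33).  We report the
values our stated convention produces rather than shrinking the prominence
cutoff until the numbers match, since any cutoff below 1 mV would be
justified only by its outcome.

## Fast-slow decomposition

Because $h$ is super-slow it is frozen at its burst average
(`average_h()`, a trapezoidal mean snapped to whole burst cycles), and the
slow drive is collapsed into one parameter
$g_{\mathrm{CANTot}} = g_{\mathrm{CAN}} f([\mathrm{Ca}])$.  The fast
subsystem is the $(V, n, \varphi)$ system with
$I_{\mathrm{CAN}} = g_{\mathrm{CANTot}}(V-V_{\mathrm{Na}})$.

**Equilibria.**  At a fast-subsystem equilibrium $n = n_\infty(V)$ and
$\varphi = V/k_2$ exactly, so the balancing conductance is a closed-form
function of $V$.  The whole S-shaped equilibrium curve is therefore
parameterized by voltage — no root-finding — with the 3x3 Jacobian
(analytic, validated against central differences) classifying stability
pointwise.  Folds are roots of $dg_{\mathrm{CANTot}}/dV$; the subcritical
Hopf is the zero crossing of the complex pair's real part, refined by
root-finding; criticality is probed by integrating a small perturbation on
the unstable-focus side and asking whether it saturates near the
equilibrium (supercritical) or escapes (subcritical).  A general
pseudo-arclength continuation (`continue_equilibria()`) cross-validates
the closed form to 1e-8; the two routes are independent.

**Cycles.**  The stable limit-cycle branch is tracked by warm-started
attractor integration with the period measured from mid-range voltage
upcrossings; branch endpoints are refined by bisection on "a cycle with
period below $2\times10^4$ ms exists".  Toward high conductance the branch
ends at the fold of limit cycles (LPC), where the stable cycle meets the
unstable cycle born at the subcritical Hopf; that unstable segment is
continued by damped-Newton single shooting (solving the period map plus a
voltage-extremum phase condition), which works for repelling orbits, with
Floquet multipliers from a finite-difference monodromy matrix.  Toward low
conductance the branch terminates with period blow-up, classified SNIC if
the blow-up parameter coincides with an equilibrium fold within 1e-3
(saddle-node on the invariant circle) and homoclinic (HC) otherwise.  The
period-blow-up threshold $2\times10^4$ ms sits two decades above typical
spiking periods; the HC location is resolved by period blow-up only, not
by boundary-value continuation.

**Burst labels.**  Combining diagram and trajectory: when the quiescent
phase sits on the lower branch the hysteresis loop engages the fold and
the burst is `subHopf/homoclinic via fold/homoclinic` (HC termination) or
`subHopf/fold cycle via fold/circle` (SNIC termination); when the
low-potential rest is gone the rest state is lost at the subcritical Hopf
and spiking at the LPC, `subHopf/fold cycle`.  Fold labels F1/F2 are
assigned by conductance rank (F1 at the larger conductance, the jump-up
knee); at strongly stimulated presets the second formal fold of the
closed-form curve lies at negative conductance and is reported as such.

## Two-parameter curves

Curves in the $(g_{\mathrm{CANTot}}, h)$ plane are computed by per-$h$
scans of the same one-parameter machinery rather than bordered-system
codimension-2 continuation: the closed form makes per-$h$ solves cheap and
exact, and the curves' role is geometric (which curves the slow trajectory
crosses).  The homoclinic curve is explicitly an approximation — the
contour of cycle termination — and is labelled as such.  Crossings are
found by interpolating each curve as $g(h)$ and locating sign changes
along the projected slow trajectory
$(g_{\mathrm{CAN}} f([\mathrm{Ca}](t)),\, h(t))$.

With increasing induction gain $k_1$ the closed-form curve keeps both
folds (the bifurcation structure is preserved) while the lower branch
moves toward smaller conductance; the apparent rightward motion of the
middle branch in cross-condition comparisons arises because each condition
is analyzed at its own, smaller, burst-averaged $h$.

## Calcium subsystem

The $([\mathrm{Ca}], l)$ pair has an analytic $l$-nullcline
$l = K_d/(K_d+[\mathrm{Ca}])$ and a calcium nullcline solvable in closed
form for $l$ at each calcium level; knees are extrema of that branch
function.  At IP3 = 1.2 uM the subsystem has a relaxation oscillation
(slow crawl along the nullcline branches, fast jumps at the knees) whose
period equals the full model's burst period to within 10% — the slow
oscillator paces the burst.  An IP3 scan flags oscillation by sustained
calcium amplitude above 0.005 uM over the trailing half of a 150-200 s
run; the window found brackets 1.2 uM and excludes 0.5 and 2.0 uM.  The
map between the SNIC conductance and the SNIC calcium level is the exact
Hill inversion `gcan_to_ca()` / `ca_to_gcan()` (round-trip error below
1e-12).

## Problem sizes and defaults

Analysis windows are 40 s of model time after a 20 s transient (about 20
burst cycles); sweeps classify 52 s runs per grid point and bisect over
the stated bracket, which keeps each threshold to 8-12 simulations.
Equilibrium curves use a 0.05 mV voltage grid; cycle branches use 25-60
parameter points with bisection refinement to 1e-4.  These sizes were
chosen so that every quantity reported is converged at the tolerances the
tests assert (tolerance-halving and grid-doubling leave results unchanged
at those tolerances) while a full run of the suite stays at desk scale.

## What the model world does and does not show

All "data" here are trajectories of the deterministic model itself; there
is no measurement noise, channel stochasticity, or network input.  Passing
tests therefore demonstrate the internal consistency of the analysis
pipeline and the reproducibility of the published model quantities — not
that a biological pre-BotC neuron behaves this way.  Known limitations:
the gating appendix forms are adopted from the parent models, not
reprinted in the source; figure-read constants ($T_n$, the plateau-onset
thresholds) are surfaced next to computed values where they disagree; the
homoclinic curve is a period contour, not a continued homoclinic orbit;
and no two-compartment or network variants are included.
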