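---
title: "Excitability class and delayed autaptic feedback in the Morris-Lecar neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excitability class and delayed autaptic feedback in the Morris-Lecar neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlautapse)
```

## The model

`mlautapse` simulates a two-variable Morris-Lecar (ML) membrane model,

$$C \dot V = I_{app} - g_{Na}\, m_\infty(V)(V - E_{Na}) - g_K\, w\,(V - E_K)
           - g_L (V - E_L),$$
$$\dot w = \phi_w\,\frac{w_\infty(V) - w}{\tau_w(V)},$$

with instantaneous sodium activation
$m_\infty(V) = \tfrac12[1 + \tanh((V-\beta_m)/\gamma_m)]$, potassium steady
state $w_\infty(V)$ of the same form with $(\beta_w, \gamma_w)$, and
voltage-dependent recovery time constant
$\tau_w(V) = 1/\cosh((V-\beta_w)/2\gamma_w)$. Units are ms, mV,
$\mu$A/cm$^2$, mS/cm$^2$ and $\mu$F/cm$^2$ throughout; $\phi_w$ is a
dimensionless rate multiplier, so only the ratio $\phi_w/\tau_w$ — a rate in
1/ms — enters the dynamics.

Two presets share every constant ($g_{Na} = g_K = 20$, $g_L = 2$ mS/cm$^2$;
$E_{Na} = 50$, $E_K = -100$, $E_L = -70$ mV; $C = 2$ $\mu$F/cm$^2$;
$\beta_m = -1.2$, $\gamma_m = 18$, $\gamma_w = 10$ mV; $\phi_w = 0.15$)
except the half-activation voltage of the recovery variable:

* **type II** ($\beta_w = -13$ mV): the resting state loses stability
  through a subcritical Hopf bifurcation as constant current increases, and
  repetitive firing appears at a nonzero frequency;
* **type III** ($\beta_w = -25$ mV): the resting state stays stable for
  every constant current in the physiological range; a current step evokes
  at most one spike at onset (phasic firing).

### The recovery time-constant variant

Two readings of the $\cosh$ argument circulate for this model:
$\tau_w = 1/\cosh((V-\beta_w)/2\gamma_w)$ (the standard ML form) and
$\tau_w = 1/\cosh((V-\beta_w)/\gamma_w)$. Both are implemented behind the
`tau_w_variant` switch of `ml_params()`. The package adjudicates between
them by the type II Hopf current: with the factor-2 form the bifurcation
sits at $I_H \approx 42.80$ $\mu$A/cm$^2$, matching the reference value
42.797 to 0.01%, whereas the no-factor form puts it at 46.39. The factor-2
form is therefore the default; the other variant remains available for
sensitivity checks.

## The delayed excitatory autapse

An autapse — a synapse of the neuron onto itself — feeds the membrane a
delayed, activity-dependent current:

$$I_{syn}(t) = -g_{syn}\, s(t-\tau)\, (V(t) - E_{syn}), \qquad
  \dot s = \alpha\, \Gamma(V - \theta_{syn})\,(1-s) - \beta s,$$

with release sigmoid $\Gamma(x) = 1/(1+e^{-10x})$. Defaults
$E_{syn} = 30$ mV (excitatory), $\theta_{syn} = 10$ mV (release only during
a spike), $\alpha = 12$ 1/ms (taken as a rate for dimensional consistency of
the kinetics). The delayed quantity is the activation $s$ alone; the voltage
in $I_{syn}$ is instantaneous, and pre- and postsynaptic potentials are the
same $V$. The three control parameters are the conductance $g_{syn}$, the
delay $\tau$ (synaptic processing time), and the decay rate $\beta$:
NMDA-receptor deactivation spans roughly 10–100 ms, which $\beta$ between
1 and 0.01 1/ms covers. Smaller $\beta$ means a slower-decaying, more
sustained — and on time average *stronger* — excitatory current.

## Integration scheme

Trajectories are advanced by the classical fixed-step fourth-order
Runge-Kutta scheme (default $h = 0.01$ ms), implemented in C++. The delayed
activation $s(t-\tau)$ is read from the history buffer of already-computed
grid samples, with linear interpolation because the half-step stage times
never align with the grid; $\tau$ need not be a grid multiple. The pre-run
history is $s \equiv 0$ for $t \le 0$ — no spikes before the run — so in
every autapse study the first spike is evoked by an explicit trigger
stimulus (1.5 ms, 100 $\mu$A/cm$^2$). For $\tau < h$ a stage lookup can
reach past the newest stored sample and is clamped to it; all study
conditions use $\tau \ge 1$ ms, far from this edge. A run whose state
becomes non-finite aborts with the failing time.

Numerical checks built into the test suite: starting at the solved resting
state stays there to $10^{-6}$ mV; a zero-conductance autapse reproduces
the autapse-free model bit-exactly (the feedback term is exactly zero, so
the arithmetic is identical); halving $h$ on a smooth 100 ms run shrinks
the endpoint error by a factor between 10 and 22, consistent with fourth
order; and a sharp-tolerance adaptive DDE solver (`deSolve::dede`,
tolerances $10^{-10}$) reproduces the same spike count with spike times
within 0.05 ms over a 250 ms autapse run.

## Stimulus protocols

`stimulus_protocol()` describes the piecewise-constant applied currents
used throughout: constant holds, single rectangular pulses, and periodic
brief-pulse trains (1.5 ms pulses at an 11.5 ms period). Pulse windows are
half-open $[t_0, t_0 + \Delta t)$, so a sample exactly at a pulse end takes
the baseline — this matters only at grid-aligned edges. All bundled
protocols start pulses at 50 ms so the resting state is visible first; the
onset is a presentation choice with no effect on the post-trigger dynamics,
which are autonomous. These protocols are the package's synthetic-input
generator: they emulate idealised current-clamp stimulation with perfectly
rectangular, noise-free pulses. Real current injections carry electrode
noise and finite rise times, and real synaptic bombardment is irregular, so
passing tests demonstrate the deterministic skeleton of the dynamics, not
robustness to biological variability.

## Spike metrics and classification

Spikes are upward crossings of 0 mV separated by at least 1 ms; action
potentials here overshoot 0 mV by tens of mV while subthreshold
oscillations stay well below, so detection is insensitive to the exact
threshold. (The synaptic release threshold of 10 mV plays a different role
and is not reused for detection.) A run is **repetitive** if spikes persist
into the final settle window (default 200 ms), **transient-then-rest** if
it spiked but fell silent, and **resting** otherwise. The steady interspike
interval (ISI) is the mean ISI over the terminal steady window
(default 300 ms).

Autapse-driven repetitive firing is labelled by mechanism:

* **case-1** — entrainment: the delayed current arrives as discrete pulses
  and each pulse evokes the next spike, so the steady ISI tracks the delay
  $\tau$ (within 15%);
* **case-2** — sustained drive: the current holds the neuron beyond its
  rest-to-spiking transition and the ISI is set by the limit-cycle period
  instead.

Entrainment takes precedence in the classifier: a slowly decaying autapse
can keep $I_{syn}$ above the Hopf current most of the time even while each
spike is still evoked by the delayed pulse (the type III,
$\beta = 0.1$, $\tau = 15$ ms regime is exactly this — the current exceeds
$I_H$ 98% of the time yet the ISI is 15.7 ms $\approx \tau$), so the
fraction of time above $I_H$ corroborates a case-2 label but cannot
override an ISI that tracks the delay.

## Bifurcation analysis

Equilibria are roots of the scalar current balance along
$w = w_\infty(V)$, bracketed by a 400-point sign scan over $[-90, 60]$ mV,
refined by `uniroot` and polished with three Newton steps (residual below
$10^{-10}$). Stability comes from the analytic $2\times2$ Jacobian;
focus/node labels follow the discriminant, which classifies the type II
rest at $I_{app} = 0$ as a stable *node* (real eigenvalues) even though
phase-plane intuition often calls it a focus — the spiral structure only
appears at intermediate currents.

`find_hopf()` bisects the sign of the larger eigenvalue real part; at the
crossing it verifies nonzero imaginary parts (trace zero, determinant
positive — the planar Hopf condition). For type III the absence of any sign
change over $I_{app} \in [0, 200]$ $\mu$A/cm$^2$ is the expected outcome;
200 doubles the largest current used in any protocol and stands in for the
unquantified "physiological range".

The fold (saddle-node) of limit cycles is located by hysteresis
continuation: establish the stable cycle at $I_{app} = 100$, walk the
current down in 1 $\mu$A/cm$^2$ steps re-seeding each 500 ms probe from the
previous final state (so the trajectory stays on the cycle branch inside
the bistable window), then bisect the smallest current at which the
repetitive classification persists, to a 0.01 bracket. Probes discard a
100 ms settle window. The unstable cycle between fold and Hopf separates
the coexisting attractors; it can be visualised by time-reversed
integration (valid for planar flows) but is not computed by default.

## Parameter-plane scans and the firing border

`scan_tau_gsyn()` classifies a grid of $(\tau, g_{syn})$ cells at fixed
$\beta$, each cell an independent triggered run (600 ms with a 200 ms
settle window by default — long enough that every regime in the scanned
plane has settled, short enough that a 60$\times$60 grid stays a
desk-scale computation; both are configurable). Determinism makes cells
exactly reproducible standalone. The qualitative structure: at
$\beta = 1$ both presets fire over a similar region; as $\beta$ decreases
the firing region grows for type II and shrinks for type III, vanishing
entirely for $\tau < 30$ ms at $\beta = 0.01$.

`firing_border_in_beta()` bisects the decay rate between firing and
non-firing at fixed $(g_{syn}, \tau)$, after a geometric coarse pre-scan
that verifies the classification changes exactly once; non-monotone
patterns are reported with the pre-scan table rather than silently
bisected. This is the paradoxical-excitation measurement: for type III at
$g_{syn} = 3$, $\tau = 4$ ms, fast-decay (weaker-averaged) feedback
sustains firing while slow-decay (stronger-averaged) feedback does not.
The measured border is $\beta \approx 0.36$, a sharp transition (three
spikes below it, sustained firing above) that is invariant to doubling the
run length and to refining the step to $h = 0.002$ ms.

`beta_sweep_avg_current()` quantifies "stronger": the trapezoidal time
average of $I_{syn}$ over a fixed window, by default one ISI of the
matched $\beta = 1$ reference run taken from its third spike. The window
is anchored early, just after the autaptic loop engages, because that
epoch exists in every run of the sweep — including those whose firing
later dies — whereas any late window would find the activation fully
decayed in non-firing runs and understate their drive. The same absolute
window is applied to every $\beta$, and is returned with the results. The
average rises monotonically as $\beta$ falls for both presets, which is
precisely the paradox for type III: more average excitation, less firing —
type III spikes respond to the *rate of change* of the current, and a
slowly decaying current changes too little between spikes to evoke the
next one.

## Problem sizes and defaults

| Quantity | Default | Why |
|---|---|---|
| Integration step $h$ | 0.01 ms | resolves the ~1 ms spike upstroke with fourth-order headroom |
| Autapse run length | 1000 ms | ~60–190 spikes at the observed ISIs; steady stats use the final 300 ms |
| Settle window | 200 ms | longer than any observed transient (slowest decay: $1/\beta = 100$ ms) |
| Fold probes | 500 ms, 100 ms discarded | ~75 cycles near the fold; bisection bracket 0.01 $\mu$A/cm$^2$ |
| Scan cells | 600 ms, 200 ms settle | grid fidelity at desk-scale runtime |
| Hopf bracket | $10^{-4}$ $\mu$A/cm$^2$ | far below the 0.5% comparison band |

## Known limitations

Single compartment, single neuron; no channel noise, no synaptic
plasticity, no temperature scaling, and no type I excitability preset.
Spike times are reported at grid resolution ($h$), which bounds ISI
precision at 0.01 ms under the defaults — ample for all statistics here.
The continuation is one-parameter; codimension-2 structure (e.g. how the
Hopf point moves with $\beta_w$) is out of scope. The classifier's 15%
entrainment band and the 0.5 current-fraction threshold are heuristics
chosen to separate the observed regimes cleanly; parameter points close to
a regime boundary can be genuinely ambiguous and should be inspected via
the trajectory, not the label alone.
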