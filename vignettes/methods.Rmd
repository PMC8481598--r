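---
title: "Closed-loop DBS in a cortex-basal ganglia-thalamus network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop DBS in a cortex-basal ganglia-thalamus network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`cbgtloop` is a testbed for adaptive deep brain stimulation (DBS). It couples
three components:

1. **The plant** — a conductance-based network model of the cortex-basal
   ganglia-thalamus circuit whose degree of parkinsonism is set by a single
   scalar `pd` in [0, 1];
2. **The biomarker** — the beta-band (13–30 Hz) power of the simulated GPi
   local field potential (LFP), estimated with sliding-window multitaper
   spectra; and
3. **The controllers** — proportional (P), proportional-integral (PI), and a
   supervisory scheme in which an on-line-trained radial basis function
   (RBF) network gradually takes over the control effort from a fixed-gain
   P/PI controller. The manipulated variable is the DBS pulse repetition
   frequency delivered to the GPi, clamped to [5, 200] Hz.

This vignette documents the model equations, the parameters a user may want
to touch, the numerical choices, and the design decisions taken where the
problem was genuinely open. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

# The plant

## Populations and single-cell models

Eight populations of 10 single-compartment neurons each: excitatory and
inhibitory cortex (`eCTX`, `iCTX`), direct- and indirect-pathway striatum
(`dSTR`, `idSTR`), subthalamic nucleus (`STN`), external and internal globus
pallidus (`GPe`, `GPi`), and thalamus (`TH`).

STN, GP (shared by GPe/GPi), TH and STR neurons are Hodgkin-Huxley-type with
membrane capacitance 1 uF/cm^2; their ionic currents and gating kinetics are
encoded both in the R-level model specifications (`neuron_model()`,
`gating_spec()`) and in the compiled integrator, and the two encodings are
cross-checked against each other (and against an independent `deSolve::lsoda`
integration) in the test suite. Gates follow either
`dX/dt = lambda_X (X_inf - X) / tau_X(v)` with sigmoid steady states
`X_inf = 1/(1 + exp(-(v + w_X)/sigma_X))`, or alpha/beta rate kinetics
(striatum). GP carries a calcium pool `dCA/dt = 1e-4 (-I_Ca - I_T - 15 CA)`
feeding its after-hyperpolarization current through `CA/(CA + 10)`. Cortical
neurons are Izhikevich cells (`dv/dt = 0.04 v^2 + 5v + 140 - u - I`,
`du/dt = a(0.2v - u)`; reset to -65 mV with `u <- u + d` above 30 mV;
eCTX: a = 0.02, d = 8; iCTX: a = 0.1, d = 2).

Two peculiarities of the cell models are worth knowing about:

* **STN bistability.** The STN model as specified has, besides its ~8 Hz
  tonic mode, a fast (~190 Hz) depolarized limit cycle that is entered when
  the cell starts hyperpolarized with its slow inactivation gates
  equilibrated. Initial voltages are therefore drawn from U(-60, -50) mV
  (gates at steady state, `CA(0) = 0.1`, `u(0) = 0.2 v(0)`), which places
  every cell in the tonic basin. The fast mode is still reachable
  dynamically under very strong sustained inhibition, which is why the
  shipped pallido-subthalamic conductance is deliberately moderate.
* **Threshold-like gates.** The STN `I_CaK` activation and the `d2` gate
  have sub-millivolt slopes; they act as switches around 0 mV and are
  handled by the integrator's gating tables without special treatment.

## Synapses

Every projection is a delayed alpha synapse: a presynaptic spike at `t_s`
contributes `S(t) = ((t - t_s - t_d)/tau) exp(-(t - t_s - t_d)/tau)` after
the transmission delay `t_d`, with `tau = 5` ms network-wide, and the
current is `g (v_post - E_syn) S`. The integrator implements the identical
kernel as a pair of linear filter states per postsynaptic cell, with spike
arrivals queued in per-projection delay lines; `synapse_drive()` exposes the
explicit kernel sum, and the equivalence of the two routes is covered by the
decoupling and convergence tests.

Reversal potentials default to 0 mV for excitatory and -85 mV for
inhibitory projections. A uniform-reversal variant
(`network_config(esyn_literal = TRUE)`, CLI flag `--uniform-esyn`)
forces -85 mV everywhere; it is provided because that convention appears in
parts of the literature this model family descends from, but it makes the
nominally excitatory projections inhibitory and is not the default.

## Connectivity and default parameters

The nucleus-level topology is fixed: the direct
(eCTX-dSTR-GPi-TH-eCTX), indirect (eCTX-idSTR-GPe-GPi-TH-eCTX) and
hyper-direct (eCTX-STN-GPi-TH-eCTX) pathways, reciprocal STN-GPe and
eCTX-iCTX coupling, and GPe-GPe collaterals. Per-connection conductances,
delays, fan-in and wiring, the bias currents `I_app` (GPe 2, GPi 3,
TH 0.7 uA/cm^2, eCTX 5 with seeded heterogeneity), and the cortical noise
level are **editorial defaults of this package**: they are not uniquely
determined by the published description of this model family, and they were
chosen so that the healthy and parkinsonian states express the expected
phenomenology (see "What the defaults were tuned for"). Every one of them
can be overridden through `network_config()` or a YAML configuration file.

Wiring is a deterministic ring: postsynaptic cell *i* receives from `fan`
consecutive presynaptic cells starting at a fixed offset. The GPe
collaterals use fan 6 (each cell inhibits its six ring neighbours), which
under the parkinsonian collateral conductance produces the clustered
anti-phase bursting that drives the beta rhythm.

## The parkinsonism variable

`apply_parkinsonism(config, pd)` maps `pd` onto exactly three parameters:
striatal M-current conductance `g_m = 2.6 - 0.9 pd`, cortico-striatal
coupling `g_CTX,STR = 0.07 - 0.044 pd`, and intra-GPe coupling
`g_GPe,GPe = 0.0125 + 0.0375 pd`. The mapping is absolute (repeated
application does not compound). All other parameters are untouched.

Mechanistically, in this build the parkinsonian state works as follows: the
weakened cortico-striatal drive silences the striatum (removing both the
noisy striato-pallidal inhibition that decorrelates the healthy GPe and the
direct-pathway inhibition of GPi), while the quadrupled GPe collaterals
organize GPe into alternating burst clusters. The STN-GPe loop locks to
this rhythm at ~15-16 Hz, and the shared GPe/STN projections imprint it on
GPi. The result is higher STN and GPi rates, a lower GPe rate, elevated
spike synchrony, and a stable ~4 dB beta-band excess in the GPi LFP
relative to the healthy state of the same network build.

## What the defaults were tuned for

The shipped configuration was selected so that, across seeds:

* STN and GPi mean rates increase and GPe decreases from `pd = 0` to
  `pd = 1`; spike synchrony increases in STN, GPe and GPi;
* the parkinsonian GPi LFP shows a beta-band spectral peak and more
  beta-band power than the healthy LFP on every seed;
* constant low-frequency DBS (~15-30 Hz) *raises* beta power while
  frequencies above 50 Hz progressively suppress it;
* windowed beta power is stationary enough (SD ~1 dB) that the ~4 dB
  parkinsonian excess is a usable control error.

These are qualitative reproductions of the phenomenology this model family
is known for; with only 10 neurons per nucleus, absolute firing rates and
the absolute dB scale should not be over-interpreted (see "Limitations").

# The biomarker

The LFP is the arithmetic mean of the 10 GPi membrane potentials, sampled
at 1 kHz for analysis (the beta band is far below that Nyquist rate).
Beta power is computed per sliding window of 1 s advanced in 0.1 s steps:
the window is demeaned, tapered with 5 DPSS (Slepian) tapers at
time-bandwidth product 3, the one-sided multitaper PSD is formed, and the
power is integrated (summed bins x 1 Hz bin width) over 13-30 Hz. Window
timestamps are window *ends*, so each value uses only past data and the
series is causal, as feedback use requires. The DPSS tapers are computed
from the symmetric tridiagonal eigenproblem and cached; orthonormality,
spectral concentration and a Parseval check are covered by tests.

**dB convention.** Reported beta power is
`10 log10(power in mV^2) + calibration_db`, with `calibration_db = 110` by
default. The additive offset anchors the measured healthy-state level
(~9.6 dB raw under this package's conventions) to the ~120 dB operating
point conventionally reported for this model family with other spectral
packages; absolute dB levels are convention-dependent, and only
*differences* carry information (controllers and RMSE values are
offset-invariant). The offset is a `spectral_config()` knob.

Supporting biomarkers: `detect_spikes()` (upward -20 mV crossing with a
1 ms lockout, matching the integrator's on-line rule), `firing_rate()`,
`synchrony_chi()` (ratio of population-mean voltage variance to mean
single-cell variance, in [0, 1]), `bandpass_beta()` (4th-order zero-phase
Butterworth), and `rmse()`.

# The controllers

The control error is logged as `e = y_d - y` (reference minus measured beta
power, in dB). Because the plant's static gain is *negative* over its
useful range — raising the pulse frequency above ~50 Hz lowers beta power —
a textbook PID with positive gains acting on `e` is positive feedback: it
would reduce stimulation whenever beta is too high and park the command at
the 5 Hz floor. The P/PI laws therefore act on the *beta excess*
`y - y_d = -e` with positive gains, so excess beta drives the commanded
frequency up. This is the only sign convention under which the published
gain settings make the loop regulate at all, and it is applied uniformly to
P, PI and the supervisory scheme.

* `p_step()`: `u_p = kp (y - y_d)`.
* `pi_step()`: adds `ki` times the accumulated excess, with the integral
  state bounded at `200/ki` (anti-windup; an unbounded integral with a
  clamped actuator stalls recovery after saturation).
* `supervisory_step()`: `u = clamp(u_p + u_rbf, 5, 200)`; after each cycle
  the RBF is trained against the clamped command actually delivered.

## The RBF network

A 1-input / m-hidden / 1-output Gaussian network:
`h_j = exp(-||x - c_j||^2 / (2 b_j^2))`, `u_rbf = sum_j w_j h_j`. The
default input is the *reference* beta power, normalized affinely from the
configured beta range (90-150 dB) to [-2, 2] — the network acts as a
feedforward inverse plant model (desired output to required command); using
the error as input is available via `controller_spec(rbf_input = "error")`.

Training minimizes `E = (u_rbf - u)^2 / 2` by gradient descent (learning
rate 0.30, momentum 0.05) on weights, centers and widths; since
`u = u_p + u_rbf` when unclamped, the gradient signal is exactly `-u_p`,
so the network integrates the feedback term — the supervisory property that
the RBF gradually assumes the command while `u_p` fades to zero. All three
gradients are verified against central-difference differentiation to 1e-6.

Design points settled here:

* **Hidden-layer size**: the published description gives both 11 nodes and
  5-element center/width vectors; the default is m = 11 with centers spaced
  over [-2, 2] and widths 5, and `rbf_state(five_node = TRUE)` (CLI
  `--five-node`) reproduces the compact 5-node vectors.
* **Momentum form**: the momentum term is `alpha (theta(t-1) - theta(t-2))`
  for all three parameter sets. (A *sum* in place of the difference appears
  in parts of the published description; a sum grows without bound and is
  treated as an erratum.)
* **Width gradient**: the width update uses `||x - c_j||^2 / b_j^3`, the
  true Gaussian-width gradient, validated numerically.
* **Widths floored** at 0.1 to prevent division blow-up; weights start
  uniform on [0, 1], seeded.
* The RBF is updated against the **clamped** command (what the plant
  received); updating against the unclamped sum is the documented
  alternative and changes behaviour only during saturation.

# The closed loop

`run_closed_loop()` starts with a 1 s unstimulated warm-up (one full
spectral window), then iterates: simulate one stimulation period at the
commanded frequency (one 0.3 ms, 300 uA/cm^2 monophasic pulse per period,
injected into every GPi cell and nowhere else), append the GPi voltages to
the rolling 1 kHz LFP buffer, recompute beta power on the trailing 1 s
window, read the parkinsonism and reference schedules, and take one
controller step. The initial command is 5 Hz. Commanded periods are
honoured exactly (total simulated time equals warm-up plus the sum of the
periods), and the noise stream is a counter-based function of the seed and
absolute step index, so segmenting a run — or delivering zero-amplitude
pulses — reproduces the corresponding uninterrupted simulation bit for bit.

The default reference is **self-calibrated**: the measured healthy-state
beta power of the same network build (2.5 s run at `pd = 0`, windows after
the initial transient averaged), rather than a hard-coded 120 dB, because
the absolute dB scale is convention-dependent. A fixed numeric reference is
accepted wherever a schedule is.

Scenario schedules: `pd` may be constant, an arbitrary function of time, or
`"random"` (seeded uniform draws every 1 s dwell); the reference may be
constant, a function, or `"square"` — a 1 Hz square wave alternating
between the healthy level and healthy + 4 dB, i.e. between the two
operating points this plant can actually express (its parkinsonian excess
is ~4 dB; a larger excursion would be unreachable and the tracking error
would be dominated by the unreachable half-cycle).

`settling_time()` reports when the sliding-window beta power first enters
and thereafter stays within a relative band (default +/-10 percent) of the
reference. On the 120 dB-anchored scale that band is wide (+/-12 dB); the
sharper statements about control quality are the RMSE comparisons.

`frequency_sweep()` runs constant-frequency DBS (0 = no stimulation, else
5-200 Hz) over seeded trials and reports steady-window beta power;
frequency 0 reuses the identical seed and therefore reproduces the
unstimulated parkinsonian run exactly. Note that strong periodic driving
can sub-harmonically lock the GPi (e.g. 9:1 locking near 180 Hz re-creates
a 20 Hz component); the default sweep grid {0, 15, 30, 50, 100, 130, 160,
200} samples the monotone suppression range above 50 Hz.

# Numerical choices

* **Integrator**: fixed-step classical RK4, `dt = 0.01` ms by default, all
  state (membranes, gates, calcium, synaptic filters) advanced together;
  gates are clamped to [0, 1] and calcium to nonnegative values after each
  step (interpolation-level excursions only). Halving `dt` changes
  decoupled single-population traces by < 0.5 mV RMS over 200 ms; in the
  coupled network, synaptic event delivery is quantized to the step, so
  spike-phase shifts dominate and the stated bound is 8 mV RMS over 200 ms.
* **Gating tables**: voltage-dependent gate functions are evaluated through
  dense lookup tables (0.02 mV grid, linear interpolation) in the compiled
  core; the R-level specifications are exact and serve as the oracle.
* **Delays** are rounded to integer steps (minimum one step).
* **Spike detection**: upward crossing of -20 mV with a 1 ms refractory
  lockout for HH-type cells (debouncing noisy crossings); the 30 mV
  peak-reset rule for cortex.
* **Noise**: optional per-population white-noise currents (default: cortex
  only, eCTX 1.5 / iCTX 1.0 in uA/cm^2 sqrt(ms)), generated by a
  counter-based RNG keyed to (seed, absolute step), frozen within a step
  and scaled by 1/sqrt(dt) so statistics are step-size-invariant.
* **Problem sizes** used by the shipped tests and the acceptance script:
  characterization 3 seeds x 5 s per state; controller comparison 3 seeds x
  (1 s warm-up + 6 s control) per controller with the RMSE taken over the
  last 4 s on the 0.1 s spectral grid; frequency sweep 8 frequencies x 5
  trials x 2.2 s; robustness scenarios 6 s of control. These are the sizes
  at which the defaults were validated.

# What the synthetic plant does and does not show

The plant emulates the qualitative pathophysiology of the parkinsonian
basal ganglia — rate changes, synchrony increases, an emergent beta rhythm,
and the non-monotonic beta response to DBS frequency — in a deliberately
small network (10 cells per nucleus, deterministic ring wiring, cortical
noise as the only stochastic drive). Passing tests on it demonstrate that
the biomarker pipeline and the controllers behave correctly on a plant with
realistic difficulty (delayed, nonlinear, noisy, negative-gain); they do
not demonstrate efficacy on real LFP recordings, which carry volume
conduction, stimulus artifacts, nonstationary medication states and far
lower signal-to-noise. The absolute dB scale, absolute firing rates, and
the ~4 dB parkinsonian beta excess are properties of this build, not
clinical predictions.

# Known limitations

* Stimulation is an intracellular current in GPi cells; there is no
  extracellular field model, no charge-balanced biphasic waveform, and no
  electrode/hardware latency model.
* The striatum in this build *silences* in the parkinsonian state (the
  weakened cortico-striatal drive dominates the increased MSN
  excitability); the indirect-pathway rate increase seen in vivo is not
  reproduced, and the beta mechanism rests on the GPe collaterals instead.
* The published description's e = y_d - y with positive gains is
  implemented as control on the beta excess (see "The controllers"); the
  literal sign convention does not regulate this plant.
* With the 1 s spectral window, references switching at 1 Hz are at the
  edge of what the measurement chain can follow; tracking is assessed
  relative to the uncontrolled comparator, not in absolute terms.
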