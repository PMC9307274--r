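---
title: "Coordinated spike coding and the error bounding box: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinated spike coding and the error bounding box}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikebox)
```

## The model

spikebox simulates networks of `N` leaky integrate-and-fire neurons that
encode an `M`-dimensional signal `x(t)` (with `M << N`; the redundancy is
`rho = N/M`) so that a fixed linear readout can reconstruct it. Each neuron
`i` owns a unit-norm decoding vector `D_i` (a column of the `M x N` decoder
matrix `D`); the readout is the decoder-weighted sum of exponentially
filtered spike trains,

$$\hat x(t) = D\,r(t), \qquad \dot r = -\lambda r + s(t),$$

and each spike of neuron `i` therefore moves the readout by `D_i`. The
defining idea of *coordinated spike coding* is that a neuron fires exactly
when its spike reduces the readout error, which identifies its membrane
voltage with the projected error,

$$V_i = D_i^\top (x - \hat x),$$

and makes the spike rule `V_i >= T_i` a set of linear inequalities
`D^T (x - xhat) <= T`. Their intersection is a convex polytope in signal
space — the **error bounding box** — inside which the readout error is
confined. Differentiating the voltage identity yields a recurrent LIF
network with fast lateral connectivity `Omega = -D^T D`: similarly tuned
neurons inhibit each other, orthogonal ones are unconnected, antipodal ones
excite each other, and the diagonal is the post-spike self-reset
`V -> T - ||D_i||^2`.

Because all voltages are projections of one `M`-dimensional error, the
noiseless voltage vector lives in the `M`-dimensional row space of `D^T`
(`subspace_residual()` measures departures from it), and everything a
perturbation does to the network can be read as a deformation of the box:
neuron death removes a face, an excitatory current pushes a face inward, an
inhibitory current pushes it outward (where other faces usually take over),
a mistuned reset or synapse deforms a face transiently with the leak time
constant, and synaptic delays let faces "retract" for the delay duration.

A second, slower set of connections `D^T (A + lambda I) D` turns the
autoencoder into a generator of the linear dynamical system
`xdot = A x + c(t)` (`simulate_slow_network()`); the fast coordination
machinery is unchanged and keeps the spiking error bounded around the
self-generated trajectory.

## Integrator

The continuous dynamics are a stochastic differential equation integrated on
a fixed grid (default `dt = 1e-4` s). We use an *exponentially consistent*
scheme: voltages and filtered spike trains decay by `exp(-lambda dt)` per
step, and the feedforward drive enters as the increment
`F (x[n+1] - exp(-lambda dt) x[n])`, which is the exact integral
`int e^{-lambda(t-s)} (lambda x + xdot) ds` over the step. This agrees with
forward Euler–Maruyama to `O(dt^2)` per step but has one decisive property:
in the noiseless, undelayed case the identity `V = D^T (x - xhat)` holds to
machine precision at every grid point, with `xhat` computed *from the spike
list alone* by exponential filtering. The test suite asserts this to 1e-8
(it holds to ~1e-14) — with a plain forward-Euler leak the discretization
error at `dt = 1e-4` is ~1e-3 and the identity is unverifiable. Voltage
noise enters as independent Gaussian increments of standard deviation
`sigma_V * sqrt(dt)` per step.

Threshold crossings within a step are resolved one at a time ("slowing down
time"): while any non-refractory neuron is above threshold, the neuron with
the largest violation fires (exact ties to the lowest index), its self-reset
applies instantly, and its lateral effect applies instantly (no delay) or is
queued. The loop is capped at `10 N` crossings per step; hitting the cap
raises the `substep_overflow` flag — the hook for ping-pong detection — and
is deliberately not an error. With a synaptic delay `theta`, lateral
recurrence and the decoder readout are delivered at the first grid point at
or after `t_spike + theta`, at the *end* of that step, while self-resets
remain instantaneous; delayed inhibition therefore cannot veto crossings
resolved in its arrival step, which is precisely the mechanism that makes
delayed high-redundancy networks fire "uninformed" spikes.

Refractoriness (`tau_ref`, default 2 ms) suppresses spikes but lets the
voltage keep integrating; the minimum same-neuron interspike interval is
exactly `tau_ref`.

For slow networks, a raw command `c(t)` is integrated with an
exponentially weighted trapezoid. A command constructed by
`command_from_signal(signal, lambda)` carries its generating trajectory and
reuses the exact autoencoder increments with slow weights `D^T A D` (the
`lambda I` part of the slow recurrence is already contained in
`lambda x + xdot`); with `A = 0` this makes the slow simulator reduce
*bit-exactly* to `simulate_network()`. For a raw command the slow weights
are the full `D^T (A + lambda I) D`.

## Parameters, units, defaults

All times are in seconds.

| parameter | meaning | default | why |
|---|---|---|---|
| `lambda` | leak/readout rate (1/s) | 50 | 20 ms membrane/readout time constant |
| `threshold` (`T`) | error tolerance per face | 0.5 | the smallest box for unit-norm decoders: a unit spike jump exactly spans the box diameter |
| `tau_ref` | refractory period | 2e-3 | printed value |
| `dt` | integration step | 1e-4 | resolves the fastest events (delays of 0.5–1 ms) |
| `sigma_V` | voltage noise (per sqrt s) | 0 (simulator), 0.05 (benchmarks) | see calibration below |
| `delay` | synaptic delay | 0 | delays are studied explicitly |

The benchmarking noise `default_sigma_V() = 0.05` was calibrated once, by
the procedure the framework itself prescribes: sweep the free parameters
until baseline networks reproduce cortex-like statistics — low median rates
of a few Hz and interspike-interval CVs near one. At `M = 3`, `rho = 10`,
`T = 0.5`, `lambda = 50` this gives a pooled median CV of about 1.06 and
active-neuron median rates of about 3.5 Hz. Larger noise (e.g. 0.25)
drives high-redundancy networks into noise-induced ping-pong, which is the
documented failure mode of narrow boxes, not a useful operating point.

Two regimes deserve a note, because the default `T = 0.5` is *critical*:
the spike jump (length 1) equals the box diameter (2T), so a spike lands
exactly on the opposite border. Near-antipodal neurons are coupled by
excitation `~ +1`, and a spike can push a just-reset refractory neuron back
above threshold, leaving its face transiently crossed (by ~1e-2 for up to
`tau_ref`). Consequences adopted here:

* the strict "error never exceeds the maximum cross-section radius"
  property is exercised at `T = 0.7`, where a unit jump lands strictly
  inside the box and no refractory chaining can occur; there the bound holds
  at every grid point to 1e-6;
* the perturbation-asymmetry battery (`robustness_battery()`) runs at
  `T = 1` with operating points of norm 2.5: at the critical box, the bias
  of an excitatory perturbation is masked by immediate opposite-face
  crossings, which is the known narrow-box artefact rather than the effect
  under study.

The trend benchmarks over redundancy use input scale `sigma_x = 2` (the
generator's default is 1): signals must lie clearly outside the box for the
error floor to be set by the box geometry; with `sigma_x = 1` and `M = 2`
roughly a third of operating points fall inside the `T = 0.5` box, where
even a silent network meets the tolerance and the low-redundancy error gap
is diluted.

The slow-oscillator fixture uses `lambda = 10`: sustaining a rotation of
angular frequency `omega` requires a readout amplitude of roughly
`T lambda / omega`, so at `lambda = 50` a 2 Hz oscillation carried by 10
neurons at `T = 0.5` sits below its own sustain threshold and decays; at
`lambda = 10` the fixture oscillates indefinitely at the programmed 2 Hz.
Its decoder seed was chosen so that the 10 random directions cover the
circle (maximum angular gap 54 degrees).

## Input signals

Two families, matching the published protocols:

* `circular_signal()` — `x(t) = (a sin wt, a cos wt)` with analytic
  derivative;
* `ramped_slow_noise_signal()` — a Gaussian operating point
  `x0 ~ N(0, sigma_x^2 I)` reached by a linear 400 ms ramp from zero,
  followed by a slow wander: white noise smoothed twice with a centred 1 s
  moving average (truncated at the boundaries), mean-centred per dimension,
  and rescaled so its magnitude never exceeds `eta_x = 0.5`. The wander is
  applied only after the ramp, and the derivative is taken by central
  differences (no analytic form exists).

Error averages exclude the first 0.5 s of a trial (the controlled ramp
transient would otherwise dominate comparisons); the dead-network error
uses the same exclusion.

## Metrics and benchmarking conventions

* CV uses the sample (n-1) standard deviation and needs at least three
  spikes; rate and CV distributions are pooled across neurons and trials
  with equal weight per neuron. Rate medians are additionally reported over
  neurons that fired at least once (`rate_median_active`): with a fixed
  low-dimensional stimulus, the neurons whose decoders point away from it
  are structurally silent, and the all-neuron median is zero for every
  redundancy at `M = 2`.
* `performance_P` rescales a perturbed trial's error between the paired
  unperturbed trial (`P = 1`) and a dead network (`P = 0`). Paired trials
  share the decoder draw, the signal draw and the noise stream, all derived
  deterministically from `(master seed, trial index, stream)`; the whole
  benchmark is a pure function of the master seed.
* Ping-pong is operationalized as `detect_pingpong()`: total spikes above
  `c_pp = 5` times a healthy reference count, or a sub-step overflow. The
  analytic reference is `expected_spike_count() = lambda * int ||x|| dt`,
  from the observation that every spike moves the readout a unit length and
  the readout must continuously offset its own leak.
* The anti-ping-pong tuner grids over widening factors (`1 + k/4`) or
  pruned excitatory pairs (steps of `N^2/40`) until a seed battery is
  clean, and reports the smallest clean value; batteries use noiseless
  networks so the delay effect is isolated, and trials of at least 2 s to
  avoid false negatives.

## What the synthetic generator does and does not emulate

All inputs are synthetic by design (the framework is a theory instrument):
decoders are isotropic random unit vectors or structured Gabor patches,
signals are low-dimensional and slowly varying, noise is white and
per-neuron independent. Passing tests therefore demonstrate the internal
consistency and the published phenomenology of the model — bounded error,
robustness asymmetry, delay-induced instability and its remedies — not
properties of biological recordings: there is no Dale's law, no conduction
heterogeneity, no correlated noise, and no plasticity of the decoders.

## Degenerate inputs and edge cases

Open boxes (rays that hit no face) report infinite cross-section radii
rather than erroring; killing every neuron is an error; fewer than three
polygon decoders cannot close a 2-D box; a zero time-averaged readout makes
the sphere correction undefined; non-finite voltages abort the simulation
with the offending time step. `max_total_spikes` lets callers truncate
runaway simulations early; truncation is flagged and counts as ping-pong.

## Known limitations

* At the critical box `T = 0.5` the circumradius bound and the excitatory
  bias are confounded by opposite-face crossings (see above); analyses near
  that regime should widen the box or prune antipodal excitation.
* The windowed ("temporary") variants of reset, synaptic and pruning
  perturbations share one alternate-connectivity window per run, and a
  windowed delay change is not supported.
* Box-widening found by the tuner can be degenerate for low-dimensional
  signals: a box wider than the signal norm is trivially quiet. The pruning
  mode is the informative remedy at `M = 2`, and both are exposed.
* Problem sizes in the shipped tests are desk-scale by choice: trials of
  2 s at `dt = 1e-4`, networks up to `N = 100`, batteries of 5–20 trials.
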