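---
title: "Spiking neural networks for multi-scale heart-rate monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking neural networks for multi-scale heart-rate monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrsnn)
```

`hrsnn` simulates an always-on neuromorphic pipeline for heart-rate (HR)
monitoring from photoplethysmography (PPG): spike encoding through a band-pass
filter bank and leaky integrate-and-fire (LIF) neurons, a population decoder
for instantaneous HR, three spiking state machines for HR-zone and trend
detection, accelerometer-based motion-artifact removal, and an
activity-dependent power model of the target mixed-signal hardware. This
vignette explains the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic benchmarks do and do not show.

## The synthetic PPG model

A beat is a point moving on the unit circle with angular velocity
$\omega(t) = 2\pi\,\mathrm{HR}(t)/60$; the PPG sample is the sum of two
Gaussians in the polar angle $\theta$,

$$z(t) = \sum_{i=1}^{2} a_i \exp\!\left(-\frac{(\theta(t) - \theta_i)^2}{2 b_i^2}\right),
\qquad \theta(t) = \mathrm{atan2}(y, x),$$

one Gaussian for the systolic peak and one for the diastolic shoulder. The
default parameters ($a_1 = 0.19$, $a_2 = 0.07$, $b_1 = 0.42$, $b_2 = 0.5$,
$\theta_1 = -0.7$, $\theta_2 = 0.4$, $t_0 = 0.403$ s) are values fitted to
real resting pulses. Two modelling choices matter:

* **Circular coordinates.** `(x, y)` must trace an actual circle
  ($x = \cos\psi$, $y = \sin\psi$) for $\theta$ to sweep; with both
  coordinates equal to the same cosine the angle would be constant.
* **Accumulated phase.** For time-varying HR the phase is the integral of
  $\omega(t)$, never an instantaneous substitution, so HR steps do not
  produce phase discontinuities (`generate_ppg()`).

The model has a continuous *gauge freedom*: shifting $t_0$ by $\delta$ while
rotating both centers by $-\omega\delta$ leaves the waveform unchanged, so
$t_0$ and the $\theta_i$ are only identifiable jointly. `fit_pulse_params()`
estimates all seven parameters by Levenberg-Marquardt least squares on one
detected pulse; `align_pulse_fit()` fixes the gauge at a reference $t_0$
before parameters are compared. An alternative reading of the width
parameter (width $= 2b_i$) is exposed as `ppg_pulse_spec(width_is_2b =)`.

Noise is added by `add_noise()`: white Gaussian noise is shaped in the
frequency domain by $f^{\alpha/2}$ ($\alpha$ = 0 white, -1 pink, -2 brown,
+1 blue, +2 violet; DC bin zeroed) and renormalized so the empirical noise
power equals $P_\mathrm{signal} \cdot 10^{-\mathrm{SNR}/10}$ exactly.
Frequency-domain shaping was chosen over filtering because the exponent is
then exactly controllable; the calibration is verified by periodogram
regression in the test suite.

What the generator does *not* model: respiration, dicrotic-notch physiology
beyond the two-Gaussian shape, beat-to-beat variability, and sensor optics.
Benchmarks on it therefore exercise the architecture's frequency selectivity
and dynamics, not robustness to physiological morphology changes.

## Preprocessing: signals to spikes

`preprocess_pipeline()` standardizes the input, splits it with causal
Butterworth band-pass filters, full-wave rectifies, amplifies, and injects
each channel as current into one LIF neuron per band:

* **Bands.** The wide set is 60-82, 82-105, 105-128, 128-150 bpm
  (e1-e4, converted to Hz by /60); the narrow set is 60-80, 80-88, 88-96,
  96-150 bpm. The decoder adds two boundary filters one band-width beyond
  each end so the rate profile stays well-formed at the range edges.
* **Filters** are causal (`signal::butter` + `signal::filter`) because an
  always-on wearable cannot look ahead; zero-phase filtering is not used.
  Orders 1, 2 and 4 are the studied values.
* **Normalization.** `standardize_waveform()` emulates the front-end's
  input-range normalization (LNA + programmable-gain stage): gain 8 and
  threshold 1 refer to a unit-RMS signal. The decoder uses the *adaptive*
  variant (10 s sliding window), an automatic gain control, because with
  whole-record normalization the local scale depends on the HR mix of the
  record and the LIF operating point drifts.
* **LIF convention.** Membrane dynamics are $dv/dt = (I - v)/\tau$, so a
  constant current's steady state is $v = I$ and the inter-spike interval is
  $\tau\,\log(I/(I - V_\mathrm{thr}))$. This is the normalization under
  which the stated operating point ($\tau = 24$ ms, $V_\mathrm{thr} = 1$,
  gain 8) actually spikes at tens of Hz on unit-RMS signals. Integration is
  exact per sample for piecewise-constant input, which removes time-step
  sensitivity at 125-256 Hz input rates. Reset potential 0 and refractory
  period 0 are defaults (both unstated upstream and configurable).

## The network simulator

`simulate_network()` is a clock-driven simulator (Rcpp kernel) for recurrent
LIF populations with exponentially decaying synaptic currents: a presynaptic
event adds the connection weight to the target's synaptic accumulator, which
decays with the synapse's time constant. Defaults: `dt` = 0.1 ms (at least
100 times smaller than the fastest synaptic time constant), slow synapses
100 ms (recurrent excitation, inputs; these give the hundreds-of-milliseconds
integration that stabilizes zone selection), fast synapses 10 ms
(inhibition). Connectivity is Bernoulli per neuron pair
(`realize_connectivity()`), so in-degrees are binomial. Device mismatch is
emulated as multiplicative Gaussian jitter (CV 0.2 by default) on membrane
time constants, thresholds, and weights, drawn once per realization seed.
A configurable per-neuron mean-rate cap (1 kHz) aborts runs outside the
excitatory-inhibitory balanced regime with a `runaway-excitation` error
rather than silently saturating. Everything is deterministic given the
realization seed and the input seed.

`wta_rate_oracle()` integrates the winner-take-all firing-rate equations
$\tau\,\dot r_i = -r_i + f(I_i - \sum_{j\ne i} w_{ij} r_j)$ with
$w_{ij} = \gamma\,\Theta(r_j - r_i)$ as a small-instance reference: in the
strong-competition regime only the largest input stays active. Exact ties
are reported as ties rather than broken — the spiking network resolves them
through noise and mismatch, the oracle should not.

## State machines: zones and trends

All three architectures share a scaffold of four 16-neuron excitatory band
populations competing through one 16-neuron global inhibitory population,
with inputs wired at probability 0.3. The nearest-neighbor machine (nnNSM)
and the monotonic machine (monoNSM) add one disinhibition E-I block
(16 exc + 4 inh) per band. The wiring direction is the package's design
(the reference material gives probabilities, not topology): block $d_j$
projects to band $e_{j+1}$; in the nnNSM a band drives its own block plus
its neighbors' blocks, so a winner pre-excites ("gates") only adjacent
bands; in the monoNSM a band drives only the next-higher block, so only
upward transitions are enabled. The gate current is what lets a stimulated
adjacent band overcome the global inhibition that blocks every other band —
disinhibition implemented as targeted pre-excitation.

**Weights.** Connection probabilities are taken verbatim from the reference
parameter blocks (`nsm_params()`), including the per-band asymmetries.
Weight magnitudes are free parameters, tuned by a mean-field-guided grid
search (documented in `inst/extdata/nsm_weights.yaml`) with four
requirements checked across realization seeds at 20% mismatch: a stimulated
band wins and stays selected; an un-gated band cannot ignite from input
alone in the gated machines; gated adjacent transitions succeed at
task-scale input rates; and no spontaneous gate-driven drift occurs while
the winner is driven. Two findings from that tuning are worth recording:

* The WTA is deliberately *soft* (`w_ee = 0.05`): strong recurrence produces
  multi-second attractor hangs at staircase steps that dominate the tracking
  error. The zone selector holds its state while driven; holding state after
  the input disappears is the NSMs' job.
* In the gated machines the winner's own gate is what maintains the state
  after its input moves on; because the disinhibition blocks' E-I balance
  compresses their response, the own-versus-neighbor drive ratio (1.0 vs
  0.5) survives only if the blocks operate on the rising part of their
  transfer function — the block-internal weights are chosen accordingly.

Active-population rates sit near 40-100 Hz in the shipped configuration
(above the 20-40 Hz the hardware reports; with plain LIF neurons and these
wiring probabilities the blocking/transition margins could not be closed at
lower rates). `read_state()` decodes the zone per 500 ms window as the
fastest band population, provided it leads the runner-up by 10%; windows
with no clear winner read "none". The window is shorter than the slowest
transitions and longer than single inter-spike intervals.

`measure_transition_time()` reproduces the transition-speed experiment:
settle one band, stimulate another at a given rate, and report when the
challenger's rate first exceeds the previous winner's. Transition time is
non-increasing in stimulation rate; the exact stimulus behind the reported
absolute switching times is unstated upstream, so the package checks the
monotonicity property rather than a number.

## The instantaneous-HR decoder

Thirteen LIF neurons tile 60-150 bpm (7.5 bpm spacing). Each receives all
six band trains (four bands + two boundary filters) weighted by a Gaussian
of the bpm distance between neuron center and band center
(`decoder_weights()`; fan-in width 15 bpm, per-neuron total weight 0.5 —
both tuned on clean synthetic staircases and frozen). Decoding smooths the
windowed rate profile with a Gaussian kernel (8 bpm) along the bpm axis and
returns the continuous peak position (fine grid + quadratic interpolation).

The raw peak is a monotone but *non-identity* function of the true HR: band
tuning curves are asymmetric (pulse harmonics, filter skew on a linear
frequency axis) and LIF rates are nonlinear in their drive. As in any
tuning-curve population decoder, the readout is therefore calibrated once on
self-generated clean constant-HR sweeps (`decoder_calibrate()`: isotonic fit
of mean raw peak vs HR, inverted piecewise-linearly). The calibration is the
configurable neuron-to-bpm mapping of the decoder, computed at run time; on
an analog substrate it would be redone per power-on, and when the decoder is
simulated with device mismatch the calibration must be run on the same
realization. With the 4 s decoding window, the calibrated order-2, gain-8
decoder tracks a clean 470 s staircase spanning 60-150 bpm with an RMSE
under 1 bpm; the uncalibrated (spec-literal) readout reaches about 3.5-4 bpm,
and the qualitative filter-order comparison (order 2 best, order 4 worst
among 1/2/4) is a property of that raw readout. Decoded windows are compared
against the window-averaged target HR, since a windowed rate estimate cannot
resolve within-window steps.

## Motion-artifact removal

The cleaned signal is a linear combination of 16 channels — the four
band-filtered PPG channels and, per accelerometer axis, the same four band
filters. One 16-coefficient vector is shared across bands and interpreted as
a single cleaned signal split by the filter bank, so band $b$ combines its
PPG channel with the three same-band accelerometer channels (cross-band
channels are disjoint in frequency and drop out; the alternative reading, in
which all 12 accelerometer channels pollute every band, makes even perfect
cancellation worse than doing nothing). The objective
(`artifact_objective()`) LIF-encodes the combined per-band signals and
scores the mean over bands of the RRMSE between their firing-rate series
(2 s windows, 0.5 s step) and ECG-derived reference rates.
`optimize_combination()` minimizes it with Nelder-Mead from seeded random
initializations (PPG coefficients 1, accelerometer coefficients uniform in
[-1, 1]), 20 iterations per restart, 5 restarts, best vertex kept — never
worse than its own initialization. Gradient methods are avoided; the
spike-count objective is piecewise constant at small scales.

`make_motion_fixture()` builds the controlled benchmark: a unit-RMS clean
pulse signal as ECG surrogate, sinusoidal motion of amplitude 1 at a
band-interior frequency on one accelerometer axis, leaking into the PPG with
a known coefficient. Exercise-grade artifacts are comparable in power to
the pulse itself; a much weaker artifact would leave the raw objective
near-optimal and the benchmark empty. On this fixture the optimizer cuts
the objective by well over half and recovers the leakage coefficient's sign
and rough magnitude, and per-exercise calibration beats a global fit on
group-specific corruption (`optimize_grouped()`).

## Metrics and the power model

`rrmse()` is RMSE divided by the mean of the observed values —
dimensionless, zero iff equal, invariant under common positive rescaling.
For HR tracking the package reports both the dimensionless RRMSE and its
bpm-scale counterpart (RRMSE times mean target HR, i.e. the RMSE in bpm),
since the headline accuracy is conventionally quoted in bpm.

`estimate_power()` implements the activity-dependent hardware power model:
every neuron contributes its firing rate times the energy of spike
generation (883 pJ), encoding (883 pJ), per-core broadcast and routing
(6.84 nJ + 360 pJ per destination core), and pulse extension (324 pJ per
postsynaptic match). Power is linear in rates. The per-neuron core and
fan-out counts behind published subsystem powers are not stated, so those
powers are treated as inputs to energy arithmetic (`energy()` = power x
duration; `battery_energy()` = V x mAh x 3.6), and `fanout_for_power()`
reports the CAM fan-out that reconciles a measured mean rate with a given
power. Mean rates for power estimation are full-trial per-neuron means
(`raster_mean_rates()`).

`noise_sweep()` runs the staircase state task over an SNR-by-color grid
with 10 seed initializations (the documented statistics protocol), 100 s
per trial with a 4-step staircase (one step per band). Two behaviors are
architecture-specific in this simulator, and the tests check each where it
is reported: the mean-RRMSE ordering clean <= 20 dB <= 5 dB holds on the
nnNSM, whose gating makes noise-induced flicker costly; on the soft WTA the
ordering is a near-tie (moderate white noise even shakes loose occasional
sticky transitions), while pink noise — low-frequency power that reaches
the bands through rectification harmonics — degrades the WTA more than
white at the same SNR.

## Problem sizes and numerical choices

Simulations use `dt` = 0.2 ms for the state machines (versus the fastest
10 ms synapse) and 1 ms for the feedforward decoder; the acceptance-style
checks use a 470 s staircase for the decoder, 100 s trials for the noise
protocol, 4-16 s trials for the state-machine properties, and 60 s fixtures
for artifact removal. Spike times are strictly ordered; events are never
emitted outside the simulated interval; rasters, traces and metric tables
are reproducible bit-exactly given the seeds, and `run_experiment()` stamps
every output with the configuration hash and seeds.

## Known limitations

* The simulator uses plain LIF neurons, not the adaptive-exponential
  neurons of the target chip; reported behaviors are reproduced with LIF
  plus slow synapses, and state-machine rates run hotter than the hardware's
  printed 20-40 Hz.
* Synaptic weight magnitudes are this package's tuned defaults, not
  hardware values; the wiring probabilities are the reference values.
* Real multimodal datasets are out of scope: readers exist for delimited
  text records only, and every benchmark is synthetic. Passing tests show
  the architecture's selectivity, gating and robustness properties — not
  clinical accuracy on real PPG.
* Absolute transition times depend on unstated stimulus conditions; only
  their monotonicity in input rate is checked.
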