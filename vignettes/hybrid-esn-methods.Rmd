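---
title: "Hybrid-topology echo state networks: models, hardware emulation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-topology echo state networks: models, hardware emulation, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridesn)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the synthetic benchmarks do and do not show.

## The model

An echo state network (ESN) projects an input stream through a fixed
random recurrent layer (the reservoir) and trains only a linear readout.
The reservoir state `X[n]` (length `N`) evolves as

    Xc[n]   = W_up . X[n-1]                                (center neuron)
    X[n]    = f( W_in u[n] + W_down Xc[n] + W_ring rot(X[n-1]) )
    X[n]   <- alpha X[n] + (1 - alpha) X[n-1]              (leak)

where `rot` shifts the state one position around the ring (neuron `s`
receives neuron `s - 1`), `f` is `tanh` (or its piecewise-linear
hardware approximation), and `alpha` in (0, 1] is the leak rate. The
center neuron is *linear* — no activation is applied to `Xc` — and it is
excluded from the readout. Ring-only, two-way ring, center-only and
dense random reservoirs drop or replace terms accordingly.

The readout solves the normal equations in closed form,

    W_out = (Y X')(X X' + ridge I)^-1,

with `ridge = 0` honoured exactly on request and a default of `1e-8`
purely for conditioning. Internally the solve uses a linear-system
solver, never an explicit inverse; the explicit-inversion formula is kept
as the independent oracle in the test suite. The output activation is the
identity.

Two classification protocols are provided. The *threshold* protocol
(binary tasks) thresholds the single output per time step; accuracy is
the fraction of time steps labelled correctly. The *winner-take-all*
protocol (multi-class tasks) averages each output row over a segment and
assigns the class of the largest mean response, ties breaking toward the
lowest index; accuracy is the fraction of segments correct.

### Why the hybrid topology

A one-way ring reservoir has graph diameter `N - 1`: a perturbation needs
up to `N - 1` steps to reach every neuron. Adding a single hub ("center")
neuron that aggregates all states (`W_up`) and broadcasts back
(`W_down`) gives every ordered pair of reservoir neurons a directed path
of length at most 2, at a cost of only two extra synapses per neuron.
The package computes these properties on the actual generated graph
(`graph_diameter()`, `average_distance()`), with the center allowed as an
intermediate hop but never as an endpoint — the diameter-2 property is a
statement about reservoir-neuron pairs.

A note on the ring's *average* distance: for a directed ring the mean
shortest distance over ordered pairs of distinct neurons is exactly
`N / 2` (each source sees distances `1 .. N-1`). Claims of `2N/3` for
this quantity correspond to a different averaging convention that is not
reproducible from the ordered-pair definition; this package computes and
documents the standard mean.

`toroidal_report()` describes how the four connection sets (input,
output, ring, center) map onto a doubly twisted toroidal node array —
each node has eight links, four incoming and four outgoing. It is a
bookkeeping report for documentation; no physical routing is modelled.
The per-neuron link count of `incoming_links()` follows the same
bookkeeping: input, ring-in, center-down and center-up links are counted
at the node (4 for hybrid, 2 for the one-way ring), with the output tap
outgoing.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `N` | 100 | reservoir size (neurons) |
| `alpha` | 0.5 | leak rate; 1 = memoryless update |
| `washout` | 0 | leading steps per segment excluded from training |
| `ridge` | 1e-8 | Tikhonov term added to `X X'` |
| `threshold` | 0.5 | decision threshold for {0, 1} targets |
| `weight_law` | uniform on [-1, 1] | reservoir weight distribution |
| `seed` | — | fixes the reservoir draw bit-for-bit |

The leak recursion is written `alpha X_new + (1 - alpha) X_prev` — the
convention in which `alpha = 1` recovers the memoryless update. (The
alternative sign convention `(alpha - 1) X_prev` makes `alpha = 1`
inconsistent with a memoryless update and is not used.) The initial
state is the zero vector. Washout defaults to 0: with the zero initial
state and tanh dynamics, transients decay within a few steps at the
scales used here, and evaluation counts all simulation time.

Amplitude preprocessing (`preprocess = "absmax"`) feeds the network
normalized absolute values: `|x|` scaled per channel by the
training-split maximum. This is the natural front end for biosignal
amplitude tasks (rhythmic high-amplitude activity against background)
and keeps inputs in [0, 1] regardless of ADC scaling; `"none"` passes
raw signals.

## Digital (fixed-point) emulation

`mode = "digital"` emulates a register-transfer-level datapath
bit-faithfully:

* **Format.** Q(`int_bits`.`frac_bits`) two's-complement fixed point,
  default Q(10.20). Rounding is truncation toward negative infinity
  (floor at the LSB) and overflow saturates — standard RTL behaviour;
  both are configurable only through the format object so every code
  path shares one policy. The datapath width is a configuration
  parameter because deployed builds have used both Q(10.20) and
  Q(10.22).
* **Dataflow.** Weights are quantized once at load. Every multiplier
  output is quantized; the three per-neuron products are summed pairwise
  with quantization after each adder, mirroring a three-adder datapath.
  Inter-neuron values are the previous step's registered outputs.
* **Activation.** `pwl_tanh()`, a five-band odd piecewise-linear tanh
  with breakpoints at |x| = 0.5 and 1.5 and power-of-two slopes (1 and
  1/2), so hardware needs shifts only. The bands are interpreted by |x|,
  which makes the function continuous and odd; its worst-case deviation
  from true tanh is `1 - tanh(1.5)` (about 0.0949) at x = ±1.5 — the
  test suite verifies this against a dense-grid oracle.
* **Leak.** `alpha` is fixed at 0.5 in digital mode: the blend is an add
  followed by an arithmetic right shift, which is why that value is the
  hardware default.

As `frac_bits` grows the digital trajectory converges to the ideal
floating-point trajectory run with the same `pwl_tanh` activation; the
suite checks agreement to 1e-9 at 45 fractional bits and monotone
refinement across coarser formats.

## Analog emulation: mismatch as the weight generator

In the subthreshold (weak inversion) realization, a differential pair
implements the neuron: `i_x = I_max tanh(i_s R_in / (2 n V_T))`, with
`I_max` = 1 nA, slope factor `n` = 1.2 and thermal voltage `V_T` = 26 mV
by default. `R_in` defaults to `2 n V_T / I_max` so that a full-scale
input current drives the tanh argument to 1; it is configurable because
it is a genuine circuit choice, not a constant of nature.

Random reservoir weights come for free from device mismatch: a current
mirror's gain error is exponential in the threshold-voltage difference
of its two transistors, `w = r exp(dVth / (n V_T))` with
`dVth ~ N(0, (A_Vth / sqrt(W L))^2)` (Pelgrom scaling, `A_Vth` = 4
mV·µm for the 45 nm process assumed). The log-weight spread is therefore

    sigma = (A_Vth / sqrt(W L)) / (n V_T)  ≈ 2.85  at W = L = 45 nm.

Note the `n V_T` divisor: it belongs in the *log-domain* standard
deviation (it divides the exponent), and the printed 2.85 is only
reproduced with it in place. `sample_mismatch_synapses()` draws both
mirror gains per synapse (`w1`, `w2`), forms the signed weight
`w = w1/2` with a random ±1 polarity (each synapse wired to the positive
or negative neuron output with equal probability), and the bias
`b = w2 - w1/2` — the unique reading that makes the mirror-current form
`w2 I_max - w1 ix_minus` and the differential-plus-bias form coincide,
which the suite checks algebraically. Nominal mirror ratios default to
1 (minimally sized mirrors) and are configurable.

Cost models (all per the closed forms, with `A_match` = 20250 nm², the
10× minimal-sizing area that keeps threshold spread below 5%):

* neuron area `5 A_match`, power `I_max V_DD`;
* mismatch synapse area `A_match (2 + 4a)` with `a = A_var / A_match`
  (at most `6 A_match` at `a = 1`); power
  `V_DD I_max (2 eta + eta w1 + w2 + 2)`;
* baseline (deterministic, geometry-ratio) synapse expected area
  `2 A_match E[k / gcd(1/w_res, k)]` — enumerated exactly for the
  uniform law, seeded Monte Carlo for continuous laws;
* output layer area `(N M + 9) A_match`, power
  `eta N M I_max V_DD + 2 M I_bias V_DD`.

`power_report()` defaults to *median* mode (`w1 = w2 = 1`, the lognormal
median); `per_sample` mode propagates one drawn synapse per physical
synapse and exposes the mismatch-induced spread. The median/per-sample
distinction is surfaced rather than hidden because the lognormal mean at
sigma = 2.85 is astronomically larger than the median — summary power
figures for mismatch-based designs are meaningful only once the weight
statistic is stated, and no single printed total can be reconstructed
without it. Synapse counts per topology are `N K` input synapses plus
`N` (one-way ring), `2N` (two-way ring or center), `3N` (hybrid) or an
expected `c N (N - 1)` (random at connectivity `c`, self-loops
excluded) recurrent ones — hence total power is exactly affine in `N`
for ring-family topologies and quadratic for dense random connectivity,
which the suite verifies by exact polynomial fits.

## Memristor crossbar readout

The trained readout can be realized as a memristor crossbar: two devices
per reservoir output encode a signed weight
`w = R (G+ - G-) / (G+ + G-)`, magnitude strictly below `R`. The device
model is a threshold-gated semi-empirical tunneling model: sinh-shaped
conduction scaled by `(1 - gamma + g gamma)` (state variable `gamma` in
[0, 1], on/off ratio `g`), a state-change rate
`xi4 sinh(xi5 v - xi6 V_tp)` beyond the write thresholds and zero
between them, and a boundary window that seals `gamma` at 0 and 1. The
rate equation is integrated by forward Euler with a configurable pulse
duration `dt`. The `xi` fitting constants of the physical device this
family of models describes are not publicly tabulated; the defaults are
documented placeholders chosen for smooth, monotone incremental
switching and make no fidelity claim to any laboratory device.

Training (`pulse_train_readout()`) is stochastic sign-based
least-mean-squares realized entirely through write pulses: the signed
output error selects the crossbar row (excitatory row for positive
error, inhibitory for negative), each active column of that row receives
a supra-threshold pulse whose polarity follows the input sign, and
pulses are gated with probability proportional to the error magnitude
(clipped to 1). Both potentiation and depression therefore occur on each
row, which keeps device pairs away from joint saturation. The rule is
validated by its convergence property on separable data (final epoch
loss below initial, ≥ 90% threshold accuracy), not by equivalence to any
reference implementation of stochastic LMS.

## Reservoir-quality metrics

*Kernel quality* is the numerical rank of the matrix of reservoir
responses across input cases (singular values above
`max(dim) * eps * sigma_max` by default — the standard numerical-rank
rule); the ideal value equals the reservoir size. *Lyapunov exponent* is
the sum over cases of log ratios of state-space to input-space
nearest-neighbour distances (Euclidean; self excluded; ties to the
lowest index; exact duplicate inputs are an error rather than silently
skipped, since they would divide by zero). It is returned as a single
scalar per evaluation set; zero marks the edge of chaos.

## Synthetic benchmarks: what they do and do not show

Real EEG/EMG benchmark corpora are deliberately not required. The
generators emulate their *shape* so that every pipeline stage is
exercised end to end:

* `gen_eeg_like()`: single-channel segments, 23.6 s at 173.61 Hz by
  default. Class 0 is 1/f background plus a moderate alpha-band
  oscillation; class 1 adds ~3 Hz rhythmic bursts at 4× the background
  standard deviation covering 90% of the segment by default. Coverage
  matters: per-time-step accuracy is bounded above by roughly
  `(1 + coverage) / 2`, because uncovered steps of a burst segment are
  instantaneously indistinguishable from background — the default
  emulates ictal activity that spans the recording so that the task's
  ceiling is set by the pipeline, not the data. Burst amplitude,
  frequency and coverage are exposed as difficulty knobs.
* `gen_emg_like()`: 8-channel segments, 20 s at 4 kHz by default, five
  classes, each defined by a distinct per-channel Gaussian activation
  profile scaling 20–450 Hz band-limited noise under a slow envelope,
  quantized to the 12-bit ADC integer range.
* `split_segments()` cuts segments into fixed-length parts
  (tail-discard, not padding — 20 s at 4 s parts gives exactly 5);
  `train_test_split()` is stratified and seeded.

These classes are deliberately *easier* than real biosignals: passing
the held-out gates (≥ 90% threshold accuracy on the EEG-like task,
≥ 80% winner-take-all on the EMG-like task, both at the emulated corpus
sizes) demonstrates that the reservoir, readout, protocols and cost
models compose correctly — it says nothing about clinical-grade seizure
detection or prosthetic control, which depend on the real recordings'
variability. Lower leak rates (`alpha` ≈ 0.2) integrate over longer
windows and bridge brief inter-burst gaps on the EEG-like task; the
default 0.5 is kept because it is the hardware-friendly value (a right
shift) at which all headline behaviours hold.

## Reproducibility and problem sizes

Every stochastic operation takes a seed, and `run_experiment()` derives
per-stage seeds from one global seed by fixed offsets, so a single
integer reproduces a whole run; identical configs yield identical
manifests. The test suite runs the EEG-like gate at the full emulated
corpus size (200 × 4097-sample segments, hybrid N = 100) and the
EMG-like gate at the full 5 × 120 × 4 s part protocol; unit tests use
reservoirs of 4–30 neurons and segments of a few hundred samples. Graph
metrics are verified exhaustively for N = 3..200 (hybrid) and cross-
checked against a Floyd–Warshall oracle for small N. The reservoir
update loop is compiled (RcppArmadillo) and accumulates the
normal-equation moments segment by segment, so the full EMG-scale
protocol trains in tens of seconds without ever materializing the full
state matrix.

## Known limitations

* The digital path models datapath arithmetic, not logic resources,
  clocking or place-and-route; no HDL is generated.
* The analog models are closed-form static models: no transient
  simulation, short-channel corrections or temperature dependence.
* Memristor defaults are placeholders (see above); sneak paths, wire
  resistance and read disturb are not modelled.
* The generators make no claim of physiological realism (no volume
  conduction, electrode or motor-unit modelling).
* `esn` objects provide `print`, `summary`, `coef`, `predict`,
  `residuals` and `plot` methods; `simulate` is deliberately absent —
  the fitted readout is deterministic given states and defines no
  stochastic response-generating mechanism to simulate from.
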