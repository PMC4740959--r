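# hybridesn

Echo state networks (ESNs) with a hardware-friendly **hybrid reservoir
topology** — a one-way ring of neurons augmented with a single linear
center (hub) neuron — simulated across three abstraction levels:

* **ideal**: floating-point dynamics with `tanh` activation;
* **digital**: bit-faithful fixed-point emulation of an RTL datapath
  (Q(10.20) arithmetic, piecewise-linear `tanh`, shift-based leak);
* **analog**: device-statistics emulation in which the random reservoir
  weights arise from subthreshold transistor threshold-voltage mismatch
  and the readout is a memristor crossbar, together with closed-form
  area and power cost models.

The package is aimed at researchers in neuromorphic computing and
biosignal processing who want to study reservoir topologies and their
hardware realizations without access to the original recordings:
seeded generators produce EEG-like (two-class, single-channel) and
EMG-like (five-class, eight-channel) labelled signals that exercise
every pipeline stage end to end.

## The model

Only the linear readout of an ESN is trained; input and reservoir
weights are fixed random draws. The hybrid reservoir updates as

    Xc[n] = W_up · X[n−1]                                   (linear hub)
    X[n]  = f( W_in u[n] + W_down Xc[n] + W_ring rot(X[n−1]) )
    X[n] ← α X[n] + (1 − α) X[n−1]                          (leak)

and the readout is the closed-form normal-equation solution

    W_out = (Y Xᵀ)(X Xᵀ + λI)⁻¹.

The hybrid graph has diameter 2 and mean shortest distance below 2 for
any reservoir size (versus diameter N − 1 for the plain ring), at the
cost of two extra synapses per neuron. Reservoir weights in the analog
realization are lognormal with log-spread
σ = (A_Vth/√(WL))/(nV_T) ≈ 2.85 at minimal 45 nm sizing — mismatch is
the weight generator, not a nuisance.

## Worked example

```r
library(hybridesn)

ds  <- gen_eeg_like(n_per_class = 30, seed = 101)      # 23.6 s @ 173.61 Hz
sp  <- train_test_split(ds, n_train_per_class = 24,
                        n_test_per_class = 6, seed = 201)
fit <- esn(sp$train, topology = "hybrid", N = 100, alpha = 0.2, seed = 301)
summary(fit)
#> Echo state network fit
#>   topology: hybrid  N = 100  mode = ideal
#>   protocol: threshold  classes: 0, 1
#>   alpha = 0.2  ridge = 1e-08
#>   training segments: 48
#>   segment-level training accuracy: 1.0000
#>   readout |W_out|_F: 3.387e+04   residual RMS: 0.06498

predict(fit, sp$test)
#> ESN prediction (threshold protocol, 12 segments)
#>   accuracy: 0.9650 (fraction of time steps correct)
```

The held-out accuracy of 0.965 is the fraction of *time steps* at which
the thresholded readout matches the segment's class — the binary
(threshold) protocol used for seizure-style detection. Multi-class
tasks use the winner-take-all protocol instead (largest time-averaged
output per segment; see `gen_emg_like()` and `classify_wta()`).

The reservoir's interconnect properties and the analog weight
statistics are available directly:

```r
graph_diameter(fit$weights)                 # 2
average_distance(fit$weights)               # 1.9899  (< 2 for any N)
round(mismatch_sigma(process_params()), 2)  # 2.85
area_report(fit$weights$spec)               # per-block silicon area
power_report(fit$weights$spec)              # per-block power, median mode
```

See `vignette("hybrid-esn-methods")` for the full account of the
digital datapath, the mismatch synapse model, the memristor crossbar
readout and its pulse-based training, the reservoir-quality metrics,
and the design decisions behind the synthetic benchmarks.

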