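# pcwa: Parallel Cluster Wavelet Analysis for single-particle sensor traces

Single-molecule and single-particle sensors produce long photon-count time
traces in which each target appears as a short burst — often barely above
the shot-noise background. `pcwa` implements a fast, cluster-based
continuous wavelet transform (CWT) event detector for such traces: the
trace is correlated with scaled copies of a zero-mean template wavelet,

    C(t, s) = ∫ f(t') (1/√s) ψ*((t − t')/s) dt',

per-scale local maxima of the coefficient map are grouped into **macro
clusters** along the time axis (split at gaps larger than the widest
wavelet) and resolved into **star-graph micro clusters** around the
largest-coefficient centroid via a directional ellipse-overlap rule

    link(i, 0)  ⇔  (r_i + r_0)² ≥ (t_i − t_0)² + (Δt_i − Δt_0)²,
    r_i = w h N Δt_i √C'_i / √(w² N² sin²θ_i + h² cos²θ_i),

one event per micro cluster. Macro clusters are independent, so the
assignment is embarrassingly parallel and the total cost is dominated by
the per-scale convolutions — empirically linear in the trace length,
unlike serial ridge-line CWT pickers.

For multi-spot excitation (an N-spot interference pattern crossed by a
flowing particle produces an N-peak burst with peak spacing Δt = pitch/v),
the package provides the **Multi-Spot Gaussian (MSG)** mother wavelet: N
Gaussians spaced by Δt flanked by two negative skew-normal lobes whose
modes sit one spacing outside the outermost peaks. The lobes enforce the
zero-mean admissibility condition and make the wavelet sensitive to the
exact peak count, enabling peak-number multiplexing; the event scale
converts directly to particle velocity via the spot pitch.

Also included: Ricker and real Morlet wavelets; baseline detectors
(amplitude threshold, shift-multiply, ridge-line CWT); per-event
peak-number classification, velocity and intensity extraction with a
robust elliptical confidence gate; a ground-truthed Poisson trace
simulator; and an evaluation harness (greedy event matching, ROC curves,
threshold-scan method comparisons, runtime-scaling fits). See the methods
vignette (`vignettes/pcwa-methods.Rmd`) for the model, parameter defaults
and design decisions.

## Worked example

Simulate a 10-s multi-spot trace (10 µs bins, 7-spot events over a
0.3 counts/bin Poisson background), detect with the matched MSG wavelet,
and classify peak numbers:

```r
library(pcwa)

sim <- simulate_trace(kpc_config(seed = 7, duration = 10))
scales <- log_scales(1.2e-4, 1e-3, 32)          # peak spacings, seconds
fit <- pcwa(sim$trace, msg_wavelet(7), scales,
            threshold = 4.5, threshold_mode = "mad")
fit
#> PCWA detection (msg wavelet, 32 scales [0.00012, 0.001] s)
#>   trace: 1000000 bins, dt 1e-05 s
#>   1484 local maxima -> 44 macro clusters -> 41 events (threshold 4.5 x row MAD)

m <- match_events(fit$events, sim$truth,
                  tolerance = pmax(7 * sim$truth$dt_true / 2, 4e-5))
m
#> <match_result> TP 38, FP 3, FN 4
```

38 of the 42 ground-truth molecules are recovered (the misses are the
dimmest events); the 3 extra detections are weak noise clusters that a
threshold scan or the intensity–velocity gate removes. Detected scales
track the true peak spacing to a few percent, so each event's flow
velocity follows immediately:

```r
cl <- classify_events(sim$trace, fit$events[m$pairs$detected_index, ],
                      candidate_Ns = c(6, 7, 8), msg_wavelet(7),
                      spot_pitch = 2.2)
table(cl$N_best)
#>  7
#> 38
head(cl$velocity_um_per_ms, 3)
#> [1] 12.20  5.75  2.71     # µm/ms; true values 12.08, 5.90, 2.68
```

Every detected event is assigned the correct peak count (N = 7), which is
the basis of peak-number multiplexing; a Morlet wavelet run the same way
detects the events but cannot identify N.

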