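# burstrf

Receptive-field estimation for bursting thalamic neurons.

Relay cells of the lateral geniculate nucleus (LGN) and inhibitory neurons
of the perigeniculate nucleus (PGN) fire calcium-conductance bursts on top
of tonic spiking. Reverse-correlation mapping — the spike-triggered average
(STA) and spike-triggered covariance (STC) — assumes each spike is
independently stimulus-driven, which long PGN bursts (5–17 spikes over
70–100 ms) violate. `burstrf` implements the full analysis chain for such
cells, validated end-to-end on a synthetic-data generator with known ground
truth:

- **Burst detection** with the interval criteria for both nuclei
  (LGN: ≥2 spikes ≤4 ms apart after ≥100 ms silence; PGN: ≥5 spikes within
  70 ms, ≤30 ms apart, after ≥70 ms silence, terminated by an ISI >30 ms),
  shape-preserving 21-point resampling of within-burst ISI sequences, and
  Gaussian-mixture clustering that isolates the U-shaped
  (accelerating–decelerating) reticular signature.
- **Spike-triggered analysis** adapted to bursts: cardinal-spike policies,
  the group/shift STA correlation control, STC eigen-analysis with the STA
  projected out, and nested-bootstrap significance against circularly
  time-rotated surrogate spike trains.
- **LN models**: 1D (STA) and 2D (STA + STC subunit) linear–nonlinear
  cascades with cross-validated nonlinearity binning, fit on a training
  half and scored on a held-out half.
- **Evaluation**: explained variance with the finite-data and
  free-parameter bias correction

  γ = 1 − [RSS/σ² − (N−n)·N<sub>σ</sub>/(N<sub>σ</sub>−2)] /
  [TSS/σ² − (N−1)·N<sub>σ</sub>/(N<sub>σ</sub>−2)],
  σ² = Σ<sub>ij</sub>(d<sub>ij</sub>−d̄<sub>i</sub>)²/(RN(R−1)),

  a signal-power alternative, and per-subunit mutual information in
  bits/spike as the Kullback–Leibler divergence between spike-conditional
  and prior filter-output distributions, bias-corrected with the most
  non-significant subunit; synergy = I(STA,STC) − I(STA) − I(STC).
- **Spatial structure**: sparse-noise STA_ON/STA_OFF maps and their
  percent overlap, peak-dominance ratios, and reconstruction of
  dense-noise subunits as `a·STA_ON + b·STA_OFF` (STA) or
  `c·STA_ON⊙STA_OFF` (STC), scored by log10 power SNR.

The methods vignette (`vignettes/burstrf-methods.Rmd`) documents every
model, parameter and numerical choice.

## Worked example

Simulate a bursting PGN-like cell with one linear and one quadratic
subunit, detect its bursts, fit a 2D LN model and quantify information:

```r
library(burstrf)

stim <- make_gaussian_noise(c(4, 4), 4096, frame_duration = 0.020,
                            rms_contrast = 0.33, seed = 1)
truth_sta <- gaussian_blob_filter(5, c(4, 4), c(2, 2), peak_lag = 2)
truth_stc <- gaussian_blob_filter(5, c(4, 4), c(3, 3), peak_lag = 2)
cell <- ln_neuron(truth_sta, truth_stc, base_rate = 4, gain = 120,
                  quad_gain = 400, burst = "pgn_u_shaped")
rec <- simulate_response(cell, stim, n_repeats = 8, seed = 2)
rec
#> <spike_record> 8 repeat(s), 41576 spikes, 4096 frames x 20.0 ms

bursts <- detect_bursts(rec$repeats[[1]], criteria = "pgn")
bursts[[1]]
#> <burst_event:pgn> 5 spikes at 0.030 s, 42.0 ms long

fit2 <- ln_model(stim, rec, dims = 2, lag_frames = 5,
                 spike_policy = "cardinal_plus_tonic")
summary(fit2)
#> 2D LN model: 8 bins, 52 free parameters
#>   explained variance, bias-corrected: 0.620
#>   explained variance, naive ratio:    0.576
#>   explained variance, signal power:   0.624
#>   test frames: 2043, repeats: 8

w <- colSums(compute_psth(rec)$counts)
i_sta   <- mutual_info_1d(fit2$outputs[[1]], w)
i_stc   <- mutual_info_1d(fit2$outputs[[2]], w)
i_joint <- mutual_info_2d(fit2$outputs[[1]], fit2$outputs[[2]], w)
i_joint
#> mutual information: 0.475 +/- 0.017 bits/spike
synergy(i_joint, i_sta, i_stc)
#> synergy: +0.156 bits/spike (synergistic)
```

The bias-corrected explained variance (0.620) is the fraction of
stimulus-driven PSTH variance the model predicts on the held-out half,
after removing what finite repeats and the 52 occupied nonlinearity bins
would explain by chance; it agrees with the independent signal-power
estimate (0.624). The positive synergy says the STA and STC subunits
jointly carry more information about spiking than the sum of their
individual contributions. The recovered STC filter has cosine similarity
0.815 to the generator's ground-truth quadratic subunit here; dedicated
recovery tests at ≥50 spikes/dimension reach >0.9.

`run_pipeline(run_config(...))` chains all stages (simulate → detect →
classify → map → fit → evaluate) for a bank of configured cells and
returns per-cell tables; `write_report()` exports them as CSV.

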