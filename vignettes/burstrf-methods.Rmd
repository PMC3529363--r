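---
title: "Receptive-field estimation for bursting thalamic neurons: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptive-field estimation for bursting thalamic neurons: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstrf)
```

## The problem

Relay cells of the lateral geniculate nucleus (LGN) and inhibitory neurons
of the perigeniculate nucleus (PGN) fire two kinds of spikes: tonic spikes,
and all-or-none calcium-conductance bursts. Standard reverse-correlation
methods for mapping visual receptive fields — the spike-triggered average
(STA) and spike-triggered covariance (STC) — assume every spike is
independently driven by the stimulus. Long PGN bursts (5–17 spikes over
70–100 ms) violate that assumption badly: the later spikes of a burst are
triggered by the membrane dynamics, not by the frames displayed while they
fire. `burstrf` implements the analysis chain needed to map such cells
anyway: burst detection and classification, cardinal-spike handling with
shift-correlation controls, STA/STC subunit recovery with bootstrap
significance, linear–nonlinear (LN) response models with bias-corrected
explained variance, mutual-information and synergy estimates, and the
reconstruction of dense-noise subunits from sparse-noise ON/OFF maps.

Because no recordings are distributed with the package, every stage is
validated against a synthetic-data generator whose ground truth is known
exactly. The generator is first-class, tested code, not a fixture.

## Burst detection and classification

Bursts are detected from interspike intervals (ISIs) alone:

* **LGN**: two or more spikes, each ≤ 4 ms apart, after ≥ 100 ms of
  silence. The first spike of a recording counts as following infinite
  silence.
* **PGN**: ≥ 5 spikes within the first 70 ms (anchored at the first,
  *cardinal*, spike), spikes ≤ 30 ms apart, after ≥ 70 ms of silence; the
  burst ends when an ISI exceeds 30 ms. The 70 ms window is anchored at
  the cardinal spike rather than slid along the train; the anchored
  reading is consistent with bursts that last 70–100 ms while being
  terminated only by a long ISI.

To compare bursts with different spike counts, the ISI sequence of each
burst is resampled to 21 points with monotonicity-preserving piecewise
cubic (PCHIP) interpolation. PCHIP is used deliberately instead of a
smoothing or natural cubic spline: it cannot overshoot, so a U-shaped
(accelerating–decelerating, PGN-like) sequence stays U-shaped and a
monotone (decelerating, LGN-like) sequence stays monotone. A burst with a
single ISI yields a constant curve and is flagged.

Curves are clustered in the 21-dimensional space with a Gaussian mixture
model (`mclust`), the number of components selected by BIC. One numerical
subtlety: curves interpolated from k ISIs live on a k-dimensional manifold
of the 21-dimensional space, so unregularized component covariances can be
exactly singular and EM collapses. We therefore fit with `mclust`'s
conjugate prior, its scale set to the pooled covariance plus 1% of the
mean diagonal — just enough regularization to keep EM stable without
distorting the solution. The reticular signature is the cluster whose
21-point mean is most deeply U-shaped (central value below both
endpoints); `pgn_signature_cluster()` returns it.

The autocorrelogram width (at 5% of peak height, 1 ms bins, ±100 ms) is
also provided. Bursty trains have an empty 0–2 ms refractory notch, so the
width is measured as the extent of the contiguous above-threshold region
*containing the peak bin*, doubled across zero when the region reaches
lag 0. Only the PGN > LGN ordering of widths is treated as meaningful;
the absolute value depends on firing rate, which is why the ISI-shape
clustering, not the correlogram, is the classifier.

## Cardinal spikes and the shift-correlation control

Burst spikes are grouped by the stimulus frame in which they fall,
relative to the cardinal spike's frame: Group I (same frame), II (next),
III (third). If all spikes of a burst are driven by the stimulus that
preceded the cardinal spike, then the STA formed from Group II spikes
with the analysis window advanced by one frame — and Group III advanced by
two — must match the Group I STA. `group_shift_stas()` builds these maps
using one spike per group per burst (so every frame contributes equally)
and `shift_correlation()` reports cosine similarities against the
Group I/shift-0 reference. On simulated bursting cells the compensated
correlations exceed 0.99 while uncompensated ones fall to the chance
overlap of adjacent windows — which is why all receptive-field estimation
in the package defaults to tonic + cardinal spikes only
(`spike_policy = "cardinal_plus_tonic"`).

## STA, STC and the significance of eigenvalues

The spike-triggered ensemble collects the `lag_frames` stimulus frames
ending with the frame containing each eligible spike (lag 1 = coincident
frame; default 6 lags, covering 0–120 ms at 20 ms frames). The STA is the
ensemble mean. For STC, the ensemble is centred, the STA direction
projected out, and the covariance (1/(n−1)) eigendecomposed; the zero
eigenvalue created by the projection is dropped.

Significance of eigenvalues is assessed against surrogate spike trains
made by circularly rotating all spike times by a uniform random offset of
at least one lag window. Rotation preserves every ISI exactly — burst
structure included — while destroying stimulus alignment, which is
precisely what a surrogate for this null hypothesis must do. Each of the
(default 1000) surrogates runs through the full STA-projection + STC
pipeline.

Two read-outs are reported, because they answer different questions:

* **Per-rank bands** (`ci_lower`, `ci_upper`, `exceedance_indices`): the
  α and 1−α quantiles of surrogate eigenvalues at each rank. This draws
  the familiar spectrum-with-bounds figure and is calibrated rank-wise —
  a stimulus-blind cell yields ≈ 2αD exceedances in expectation (α =
  0.01, D = 80 gives ≈ 1.6). It is descriptive: with 79 ranks, a blind
  cell has an exceedance somewhere in roughly two thirds of runs.
* **The nested sequential test** (`significant_indices`): the extreme
  remaining real eigenvalue (largest; smallest for suppressive subunits)
  is compared with the matching extreme of the surrogate remainder; if
  outside, its eigenvector is projected out of the real *and* surrogate
  ensembles and the remainder is re-tested until nothing further is
  added. This controls the family-wise error at ≈ 2α per cell, so the
  set it returns — the subunits carried into LN models — is almost always
  exactly the true ones. A literal per-rank nesting was tried and
  rejected: projecting a false-positive eigen-direction out of the real
  data biases the real remainder low against the null, and the procedure
  cascades to flagging the whole spectrum.

The "most non-significant" subunit — the eigenvector whose eigenvalue sits
closest to its rank's null median — is exposed by `most_nonsignificant()`
and serves as the bias reference for the information estimates.

For sparse noise, STA_ON and STA_OFF average only the bright and only the
dark flashes preceding spikes, both stored as positive response strength
(dark maps are not sign-flipped). Their overlap is the normalized dot
product at the common peak lag, chosen as the lag maximizing the summed
power of the two maps; computing the overlap over the full spatiotemporal
volume is a configurable alternative, but the peak-lag reading matches
how spatial overlap is usually quoted.

## The LN model

`ln_model()` is the package's central fit. The recording is split into a
contiguous training half and test half with a guard gap of one lag window
(an interleaved split would leak stimulus frames across the lag window).
Filters are estimated from training-half spikes only. Filter outputs are
the dot products of the trailing stimulus window with each filter,
normalized by the absolute global maximum so ±1 marks maximal same/
opposite-sign similarity. The nonlinearity is the mean training PSTH rate
in each of n bins spanning [−1, 1] (a joint 2-D grid for STA + STC
models); empty bins are flagged, never interpolated, and prediction falls
back to the nearest occupied bin — a deterministic, monotone rule.

The bin count is chosen by cross-validation: starting at 4 bins and
stepping by 2, the search stops when test-half explained variance drops,
returning the last improving count. A single count over [−1, 1] is used
(not one per sign). On synthetic mid-noise cells the chosen count lands
around 10–12. For 2-D models the per-axis count is capped so that
expected training occupancy stays ≥ 10 frames per cell. The number of
free parameters reported for the bias correction is the number of
*occupied* nonlinearity bins; filter dimensions are excluded because
filters are estimated on the training half only.

## Model evaluation

Two explained-variance estimators are implemented. The bias-corrected
form works on the per-repeat counts `d_ij` (R repeats × N frames), their
mean `dbar`, and the model rate `m`:

$$\gamma = 1 - \frac{\mathrm{RSS}/\sigma^2 - (N-n)\,N_\sigma/(N_\sigma-2)}
                    {\mathrm{TSS}/\sigma^2 - (N-1)\,N_\sigma/(N_\sigma-2)},
\qquad
\sigma^2 = \frac{1}{RN(R-1)}\sum_{ij}(d_{ij}-\bar d_i)^2,$$

with RSS and TSS the residual and total sums of squares of the PSTH,
`n` the free-parameter count and `N_sigma = N(R−1)`. σ² is the sampling
variance of the across-repeat mean, so the two correction terms remove
exactly the part of RSS and TSS that finite repeats contribute. The
implementation verifies its two analytic limits: a perfect model on
noise-free repeats scores γ = 1, and as R grows the corrected value
converges to the naive ratio 1 − RSS/TSS. With σ² = 0 or a single repeat
the naive ratio is returned, flagged. The second estimator extrapolates
the stimulus-locked ("signal") power from the across-repeat structure and
applies the same extrapolation to the residuals; the two estimators agree
within a few percentage points on mid-noise synthetic cells.

Mutual information per subunit (bits/spike) is the Kullback–Leibler
divergence D(spike-conditional ‖ prior) between the filter-output
distribution preceding spikes and over the whole stimulus, evaluated on a
grid of bin sizes from 0.01σ to 1σ of the prior. Finite sampling biases
these estimates upward, so the same quantity computed for the most
non-significant subunit — which carries no information by construction —
is subtracted; for the joint 2-D information the bias is
I(STA, STC_nonsig) − I(STA). The reported value is the mean over the
stable bin-size range 0.15σ–0.4σ and the quoted error is the standard
deviation over that range. Bias-corrected values may be slightly negative
and are reported as-is, not clipped. Synergy is
I(STA, STC_k) − I(STA) − I(STC_k): positive for synergistic coding, zero
for independent contributions, negative for redundancy.

## Reconstruction from ON/OFF maps

The additive model `STA ≈ a·STA_ON + b·STA_OFF` (separate coefficients
for the two maps) and the multiplicative model `STC ≈ c·STA_ON⊙STA_OFF`
(pixel-wise product) are fit by Nelder–Mead simplex descent on the sum of
squared differences, on single-lag spatial maps at peak amplitude. Both
models are linear in their coefficients, so the simplex solution is
checked against closed-form least squares in the tests (the one-parameter
product model starts the simplex at the closed-form solution). Agreement
is quantified by SNR = log10(Σreal² / Σ(real−model)²); base 10 is a
documented, configurable choice, a zero model scores exactly 0, and a
zero residual is capped at 12. Disjoint ON/OFF supports make the product
model identically zero; the reconstruction then fails informatively.

Peak dominance — the ratio of the stronger to the weaker opposite-sign
extremum of a spatial map, single-peaked if > 2 — uses global extrema of
each sign with no subregion segmentation. For STC maps the overall sign is
arbitrary, so the dominant sign is reported as indeterminate.

## The synthetic-data generator

`make_gaussian_noise()` draws each checkerboard square independently from
a zero-mean Gaussian in contrast units (default 33% RMS contrast, 20 ms
frames; 20.8 ms works identically since the frame duration is a
parameter). `make_sparse_noise()` flashes one bright or dark square per
29 ms frame, visiting every (pixel, sign) pair a fixed number of times in
pseudorandom order.

`ln_neuron()` defines ground-truth cells with up to three channels: a
half-rectified linear (ON) channel, a half-rectified dark-preferring OFF
channel (emulating convergent ON- and OFF-centre relay input, and giving
sparse-noise experiments separable ON/OFF ground truth), and a full-wave
quadratic (energy-model) channel. Rates are passed through an
inhomogeneous Poisson sampler at 1 ms resolution — finer than any ISI
criterion. Bursts are all-or-none: when the standardized drive crosses a
threshold (default 1.3 SD) and the preceding silence exceeds the
profile's refractory requirement (100 ms LGN, 70 ms PGN), an ISI template
is stamped in with Gaussian jitter. The jittered sequence is re-sorted to
preserve the template's shape, so every inserted LGN burst is monotone
decelerating and every PGN burst changes sign of acceleration exactly
once. Tonic firing is suppressed during the burst and for 31 ms after its
last spike (the post-burst hyperpolarization), which keeps inserted and
detected bursts congruent. Templates: LGN ISIs {1.5, 2.0, 2.7, 3.4} ms
(5 spikes, ≈ 9.6 ms); PGN ISIs {20, 13, 7, 3.5, 7, 13, 20} ms (8 spikes,
≈ 83 ms).

What the generator does *not* emulate: spike-history effects beyond the
burst template, adaptation, correlated (naturalistic) stimuli, eye
movements, recording noise or spike-sorting errors. Passing the recovery
tests therefore shows that the estimators invert the generative model
they assume, under realistic rates and counts — not that real PGN data
are this clean.

## Problem sizes and seeds

The validation suite runs the pooled-cell clustering experiment at
7 PGN + 7 LGN cells × 30 s each over 20 seeded replicates; recovery tests
use 4×4 or 3×3 grids with 5 lags (D = 80 or 45), 4,096–8,192 frames,
1–8 repeats, and ≥ 50 spikes per stimulus dimension where the recovery
thresholds apply; the bootstrap uses 200 surrogates in tests (1000 by
default in analysis). Spontaneous rates of 4–6 spikes/s and driven peaks
of tens of spikes/s were chosen to emulate anesthetized thalamic
recordings; these are the study conditions of the synthetic experiments
and are fixed across the suite. Every stochastic stage takes an explicit
integer seed, and `run_pipeline()` reruns byte-identically from its
configuration.

## Known limitations

* The nested significance test assumes excitatory-or-suppressive subunits
  appear one extreme at a time; simultaneous near-equal eigenvalues are
  found over successive iterations but their attribution to first-pass
  ranks is by maximal overlap.
* Mutual-information estimates need enough spikes per occupied bin; the
  implementation warns rather than refusing, and the bias reference is a
  correction, not a guarantee, at very low counts.
* Filter-output normalization uses the global maximum over the whole
  series (as the similarity convention requires), which couples the scale
  of train and test halves; the nonlinearity itself is estimated from the
  training half only.
* No suppressive-subunit special handling and no independent-component
  variant of the subspace recovery.
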