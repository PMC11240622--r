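---
title: "Methods: the cardiosift ECG classification pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cardiosift ECG classification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cardiosift classifies single-lead ECG beats as normal or anomalous through a
fixed sequence of stages: denoise and detect QRS complexes, cut 600 ms beat
windows, describe each beat with three transform families, select a feature
subset with a population metaheuristic, rebalance the classes, and train a
compact convolutional classifier. This vignette explains each stage's model,
its tunable parameters, the numerical choices behind the implementation, and
what the synthetic test bed does and does not demonstrate.

## Synthetic ECG and what it emulates

`generate_clean_ecg()` builds each beat as a sum of five Gaussian bumps (P,
Q, R, S, T) at conventional offsets from the R-peak, with the R bump at
about 1 mV dominating. A Gaussian-bump template was chosen over a
dynamical-system ECG model deliberately: the analytic peak location gives
*exact* detector ground truth, which is what the detector and segmentation
tests need. R-peak indices are recorded at generation time, and a seeded
subset of beats (`anomaly_fraction`, drawn without replacement so the count
is exact) is made anomalous: the RR interval preceding the beat is shortened
by `premature_shortening` (default 0.35) and the QRS bumps are scaled by
`morphology_scale` (default 1.4) and widened by `width_scale` (default 1.5).
These three defaults are not taken from any measured dataset — they are
chosen once to mimic the premature-plus-morphology-change character of
ventricular ectopy while remaining visually distinct, and they are part of
the package's fixed study conditions.

Noise sources follow the standard taxonomy of ECG artifacts: powerline
interference (sinusoid at the mains frequency), baseline wander (a slow
sinusoid, < 0.5 Hz), muscle artifact (Gaussian white noise), and electrode
motion (step offsets at a Poisson rate). Each component draws from its own
seed sub-stream, so adding components separately or jointly gives the same
signal up to floating-point summation order (1 ulp), and adding noise never
perturbs beat placement.

What the generator does **not** emulate: realistic heart-rate-variability
spectra (RR jitter is white, sd 3 % of the mean RR), respiratory modulation,
multi-lead geometry, and pathological morphologies other than the
premature/wide/tall pattern. A perfect score on synthetic data therefore
shows the machinery is correct, not that it transfers to clinical
recordings; the WFDB reader exists precisely so real records can be run
through the identical pipeline.

## Denoising and QRS detection

All detection runs at a fixed 200 Hz processing rate (records are linearly
resampled in, and detected indices mapped back out). The band-pass filter is
the classical integer-coefficient pair: a cascaded-comb low-pass
`f(m) = 2f(m-1) − f(m-2) + g(m) − 2g(m-6) + g(m-12)` (transfer function
`(1−z⁻⁶)²/(1−z⁻¹)²`, DC gain 36, delay 5 samples) and its high-pass
companion, an all-pass 16-sample delay minus a 32-sample running-sum
low-pass (DC gain 0, delay 16 samples). These integer delays realize a
roughly 5–15 Hz passband — where QRS energy lives — only at the rate they
were designed for, which is why the processing rate is pinned at 200 Hz
rather than exposed as a free parameter. One printed form of the high-pass
recurrence circulating in the literature has a sign error that would place a
marginally stable pole at the Nyquist frequency and a nonzero DC gain; the
implementation uses the standard DC-zero form, whose measured cascade peak
sits near 8 Hz (the acceptance script recomputes this number).

After band-passing: a five-point derivative (slope, mV/s), pointwise
squaring (the conventional rectification between slope estimation and
integration), and a trailing-mean moving-window integrator. The window
length is 150 ms by default (`mwi_ms`) — the QRS duration scale; the choice
is configurable because the optimal value trades QRS-width smoothing against
T-wave merging.

Peak screening uses two adaptive thresholds maintained from running
signal-peak and noise-peak estimates (exponential averages, weights
0.125/0.875): `threshold1 = npki + 0.25·(spki − npki)` and
`threshold2 = threshold1/2`, a 200 ms refractory period, and a search-back
pass with the lower threshold when no QRS has appeared within 1.66× the
median of the last eight RR intervals. Every constant is a
`detector_config()` field. Accepted detections are refined to the local
maximum of the band-passed magnitude within ±150 ms, compensated for the
21-sample filter delay, and snapped to the raw-signal maximum; equal-height
maxima resolve to the earliest index. A flat signal returns zero detections
rather than an error.

Beat windows are `round(0.6·fs)` samples (216 at 360 Hz) in the half-open
interval `[peak − L÷2, peak − L÷2 + L)`; `L` may be even, in which case the
R-peak sits half a sample left of center. Windows that cross the record
boundary are dropped and counted. Labels propagate from ground-truth
annotations within ±75 ms.

## Per-beat features

Three transform families, concatenated (52 columns under the defaults):

* **Fractional DCT** (`fdct_*`): the orthonormal DCT-II matrix raised to
  power `a ∈ [0, 1]` through its eigendecomposition (principal branch of the
  eigenvalue powers); `a = 1` is the classical transform, `a = 0` the
  identity. Features are the magnitudes of the first `fdct_coeffs`
  (default 16) coefficients. The matrix power is cached per beat length.
* **Radon-wavelet** (`rw_*`): the Radon transform needs a 2-D input, and a
  beat is 1-D; the image chosen is the Mexican-hat scalogram (24
  geometrically spaced scales, resized to a 64×64 grid). Projections are
  taken at 0°–165° in 15° steps; each projection's single-level Haar split
  contributes its approximation and detail energy. Rotation uses bilinear
  *splatting* (each input pixel distributes its value over the four nearest
  output pixels), which conserves total mass exactly — ordinary bilinear
  resampling does not conserve the mass of spiky images, which would break
  the line-integral interpretation.
* **Fractional-wavelet** (`frwt_*`): the beat is carried to the fractional
  Fourier domain of order 0.5, and the magnitude is decomposed with a
  3-level periodized orthonormal db4 wavelet transform; each sub-band
  contributes energy, mean, and standard deviation. The discrete fractional
  Fourier transform is built on the eigenbasis of the Dickinson–Steiglitz
  DFT-commuting matrix, diagonalized separately in the even- and
  odd-symmetry subspaces (the full matrix has degenerate eigenvalues that
  would otherwise mix DFT eigenspaces) with the standard Hermite-index skip
  for even lengths. This construction is exactly unitary and additive in the
  order, which is what the tests verify; it costs an O(N³) eigendecomposition
  once per beat length (cached), affordable at beat lengths ≤ 256.

Columns are z-scored with statistics fitted on the training fold only and
reused verbatim on validation and test folds — normalization is the first
place evaluation leakage usually sneaks in. Constant columns are centered
but not scaled.

## Feature selection

`rfo_select()` is a wrapper selector driven by red-fox optimization. A fox
is a soft mask in `[0,1]^d`; its fitness is the 3-fold stratified
cross-validated accuracy of a nearest-centroid classifier on the binarized
mask (threshold 0.5; an all-false binarization forces the largest
coordinate), minus `λ·n_selected/d` with `λ = 0.01`. Nearest-centroid is
used as the surrogate because wrapper selection needs thousands of fitness
evaluations; the final network is trained once on the winning mask.

Each iteration, every fox moves toward the best-so-far by
`x ← x + β·sign(best − x)` with `β` drawn uniformly from `(0, distance]` —
tying the step to the fox's distance makes the distance computation
load-bearing rather than decorative, and makes the population contract
geometrically once exploration stops paying. The worst 10 % of foxes are
replaced with fresh uniform positions each iteration (the "migrating
individuals"), which substitutes for the published algorithm's local-hunting
phase; it is switchable off via `reinit_fraction = 0`. One dynamical note:
forcing `β` to the full distance does *not* collapse the population — the
coordinate-wise step overshoots and foxes bounce around the best — so the
contraction property holds for the sampled step, and that is what the test
suite asserts.

The planted-feature benchmark in the tests places 5 informative features
among 20 with a *total* Mahalanobis class separation of 3σ (per-feature
shift 3/√5). With a 3σ shift per feature the surrogate's accuracy saturates
after ~3 features and the sparsity penalty would then correctly discard the
remaining informative ones; spreading the separation keeps every informative
feature marginally useful, which is what a recovery benchmark should
measure.

## Class imbalance

`random_oversample()` duplicates minority rows with replacement (seeded)
until all class counts equal the majority count, keeping the original rows
in order. Class weights are `1/count` per class. The literal order —
weights computed *after* resampling, hence uniform — is the default, because
that is the published procedure; `weights_on = "raw"` gives the conventional
inverse-raw-count weights for use without resampling. Oversampling is
applied to training folds only.

## Classifier

`build_ialexnet()` assembles a 1-D AlexNet-style stack: five convolution
blocks (kernels 7, 5, 3, 3, 3; channels 12, 32, 48, 48, 32 — about 1/8 of
the canonical widths so the model trains on one CPU in minutes), ReLU after
every convolution, local response normalization after the first two blocks
(the AlexNet choice; switchable to `"none"`), and max pooling (factor 2)
after blocks 1, 2 and 5. The canonical terminal classifier stack is
replaced by a 50-unit fully-connected layer, ReLU, an output layer, and
softmax. The input is the selected feature vector; feeding features rather
than raw waveforms or scalogram images honors the pipeline order
(features → selection → classifier). Inputs shorter than 8 (the three
poolings) are rejected with the minimal admissible length; the pipeline
tops up a sparser selection mask from the largest soft coordinates instead.

Training minimizes class-weighted cross-entropy with the momentum update
`δ_{t+1} = δ_t − β∇G(δ_t) + α(δ_t − δ_{t−1})` (defaults `β = 0.02`,
`α = 0.9`, 30 epochs, batch 32), applied identically to every tensor.
Initialization is He-normal from the configured seed and batches reshuffle
from derived seeds, so loss curves are bit-reproducible. Divergence
(non-finite activations or loss) raises an error suggesting a smaller rate;
notably, local response normalization is itself a strong stabilizer, so
divergence in practice requires `norm = "none"`. Early stopping on
validation loss exists but is off by default. An interior numerical detail:
cross-entropy clamps probabilities at 1e-12 before the log.

The optional second stage, `two_stage_decision()`, only ever *revokes* a
"normal" verdict: a classifier-normal beat is confirmed only if its
preceding RR interval is within ±20 % of the running median and its Pearson
correlation with the running normal-beat template is ≥ 0.8; a
classifier-anomalous verdict passes through untouched. Both thresholds are
arguments; the defaults are conventional round numbers, tested for
sensitivity on the synthetic premature-beat fixture. With fewer than three
prior beats the classifier verdict stands alone.

## Pipeline, splits, and problem sizes

`run_pipeline()` executes the stages in order under one global seed; each
stage derives its own sub-seed through a fixed affine map, so toggling one
stage never changes another's stream. Splits are stratified 80/10/10 by
beat. Synthetic beats are i.i.d. by construction; for real multi-record
data, record-aware splitting (all beats of a record in one fold) is the
right policy and beats-level splitting here should be read with that caveat.

The standard synthetic run is ~400 beats at 70 bpm, 360 Hz, 20 % anomalous,
mild muscle noise (sd 0.02 mV); it completes in well under a minute on one
CPU and reaches ≥ 95 % test accuracy (the acceptance suite runs exactly this
configuration at seed 7). Unit tests use reduced sizes — 60–120 s records,
10–20 foxes, 10–30 epochs — chosen so the whole suite exercises every code
path in a few minutes; the sizes are test design choices, not algorithmic
limits.

## Known limitations

* The two filter recurrences are exact only at 200 Hz; other processing
  rates shift the passband.
* The Radon features use a fixed 64×64 scalogram grid; very long beats are
  downsampled and very fine time structure is lost.
* The fractional-transform eigendecompositions are O(N³) per distinct beat
  length — fine for beats, wrong tool for long windows.
* Nearest-centroid fitness assumes roughly spherical class clusters in the
  masked space; a configurable surrogate (e.g. the full network at reduced
  epochs) costs proportionally more.
* Everything measured here is measured on synthetic ECG; clinical claims
  require real, annotated recordings through the WFDB path.
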