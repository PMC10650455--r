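---
title: "Force-based surgical skill classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-based surgical skill classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During microsurgery, the force a surgeon applies through their instruments
carries information about their skill: novices are known to exert higher
forces, with greater variability and sharper force transients, than experts.
A sensorized surgical glove with a piezoresistive fingertip sensor records
this tool-tissue force as a univariate time series (newtons, 0-10 N range),
one trace per surgical trial. `forceskill` treats skill assessment as binary
sequence classification: given one trial's force trace, predict whether the
operator was an Expert (encoded 1) or a Novice (encoded 0).

The package provides the full benchmark around this task: preprocessing, a
synthetic cohort generator, six data augmentations, six sequence
architectures with a built-in training engine, two cross-validation
protocols with confusion-matrix metrics, and temporal saliency overlays.

## Preprocessing

Three steps, in a fixed order:

1. **Negative clipping.** Piezoresistive sensors report small negative
   forces during unloading; every negative sample is replaced by zero
   (`clip_negatives()`). Clipping is idempotent.
2. **Standard scaling.** `fit_scaler()` pools every sample of every
   *training* trial and computes the mean and standard deviation;
   `apply_scaler()` standardizes both training and test trials with those
   statistics. Fitting on the training folds only avoids test-set leakage;
   the scaler therefore changes whenever the test fold changes. We use the
   population convention (divide by N) for the standard deviation, matching
   common machine-learning scaler defaults; at cohort sample sizes
   (~10^4-10^5 pooled samples) the distinction from the n-1 convention is
   immaterial.
3. **Cropping / padding** (training only). Each training epoch draws a fresh
   random 300-step window from every trial (`crop_or_pad()`); trials shorter
   than 300 steps are padded with trailing zeros, and the true length is
   carried alongside so recurrent readouts can ignore the padding. At
   evaluation time trials keep their original temporal resolution.

Clipping and scaling are dataset-level preprocessing; the crop is a
training-time operation, which is why the order is clip, scale, crop.

## The synthetic cohort generator

The deposited glove dataset is not required: `generate_cohort()` emulates
its structure so every downstream module is exercisable and testable. The
generative model for one trial is

    trace = clip_[0,10]( moving_average( base + bursts + tremor ) )

* **bursts**: onsets follow a Poisson process (`burst_rate` per 100 steps);
  each burst is a triangular pulse with peak ~ Normal(`burst_amp_mean`,
  `burst_amp_sd`) and width ~ Uniform(5, 25) steps. Triangular pulses
  reproduce the sharp force peaks and sudden turning points seen in novice
  recordings.
* **tremor**: i.i.d. Gaussian jitter (`tremor_sd`).
* **moving_average**: centered, half-width `smoothness`, truncated at the
  trace edges (so a constant signal is preserved exactly). Stronger
  smoothing differentiates expert traces.

Default profiles (chosen once as plausible for the domain): experts at
baseline 0.8 N with 3 bursts/100 steps of 2.0 ± 0.5 N, smoothness 4,
tremor 0.15 N; novices at baseline 1.5 N with 6 bursts/100 steps of
4.5 ± 1.5 N, smoothness 1, tremor 0.45 N. This yields the documented
qualitative contrast (novices higher and spikier) and a cohort in which a
single threshold on mean force already separates most trials — mirroring the
report that median applied force differs significantly between classes on
the real data.

The default cohort shape is 7 experts and 6 novices (13 surgeons), 16-20
trials each (20 repetitions minus removed faulty trials), lengths 100-600
steps (the glove's sampling rate is unspecified, so time is treated as
unitless steps; trial lengths are uniform over the configured range as the
least-assumption choice). Each surgeon receives a multiplicative log-normal
random effect (sd 0.15 on the log scale) on burst amplitude, drawn once per
surgeon, so leave-one-user-out evaluation must generalize across genuinely
different individuals rather than across trials of the same individuals.

What the generator does **not** emulate: sensor drift and disconnection
artifacts, the mechanics of grape dissection, inter-trial learning effects,
or any within-trial task phase structure. Passing tests on this cohort
demonstrates that the pipeline's machinery is correct and that the models
can exploit class-separable force statistics; it does not certify
performance on real glove recordings.

## Data augmentations

Six operators, applied to 300-step training crops only, one named operator
per experiment. The probability-gated operators draw their gate per trial
per epoch.

| operator | parameters | gate |
|---|---|---|
| `rfft_stack` | keeps ⌊T/2⌋+1 real-FFT coefficients, zero-pads their real and imaginary parts to length T, stacks them under the raw trace (3 × T) | none (deterministic) |
| `augment_quantize` | 10 equally spaced levels spanning the trace's own range; nearest level, ties down | 50% |
| `augment_drift` | 5 interior anchors, multipliers 1 + U(0.1, 0.5), endpoints fixed at 1, natural cubic spline through the anchors, multiplicative | 50% |
| `augment_time_warp` | 5 disjoint ranges of ⌊T/20⌋ steps, every second sample kept inside them (2x speed), linear resample back to T | 50% |
| `augment_gaussian_noise` | additive N(0, 0.1) per sample | always |
| `augment_temporal_jitter` | 30 consecutive blocks of 10 steps, uniformly permuted | always |

Design notes. The FFT stack's spectral length is tied to T by zero-padding
so one architecture input shape serves all augmentations; the model's
input-channel count (1 or 3) is a build parameter. Because the FFT variant
is an input *representation* rather than a stochastic perturbation, it is
also applied (deterministically) at evaluation time — otherwise the trained
network's channel count could not match the test input. Drift is
multiplicative (values amplified by an extra 10-50% of their original
magnitude) rather than additive. The time-warp range length ⌊T/20⌋ and the
resample-back-to-T step guarantee that five disjoint ranges always fit and
that fixed-shape batching survives; warping a constant trace returns it
unchanged. Quantization anchors its level set to the per-trace min/max, so
at most ten distinct values remain.

## Architectures

All six models map a (channels × T) sequence to a single logit followed by
a sigmoid, and are trained with binary cross-entropy — with scalar 0/1
labels and sigmoid heads this is mathematically equivalent to a two-way
softmax with categorical cross-entropy.

* **LSTM / GRU**: four stacked layers, 64 hidden units; the classification
  reads the final layer's hidden state at the last *non-padded* time step
  (trailing zero padding would otherwise wash out the final state), then one
  affine map. GRU swaps in GRU cells and has strictly fewer parameters.
* **Bi-LSTM**: each of the four layers runs both directions at 64 units and
  concatenates them (128 features per step); the readout concatenates the
  forward state at the last valid step with the backward state at step 1.
* **CLDNN**: Conv1D(64) + ReLU + MaxPool(2) and Conv1D(128) + ReLU +
  MaxPool(2) — so the temporal axis halves twice (T/2 then T/4) — followed
  by four LSTM layers (64) and two affine layers (64 → 64 → 1). The
  convolution kernel (5, stride 1, same padding) and pooling (2, stride 2)
  are pinned as the smallest standard choices satisfying the documented
  halving; intermediate features f(1)-f(8) are exposed with shapes
  (64, T/2), (128, T/4), four of (T/4, 64), and two of (64).
* **TCN**: four blocks of Conv1D(kernel 25, stride 1, symmetric padding 12)
  → BatchNorm → ReLU → MaxPool(kernel 3, stride 1, padding 1), output
  widths 64, 32, 16, 16. Every block preserves the temporal length, so the
  final feature F(4) is 16 × T for any T ≥ 25; it is averaged over time and
  fed to an affine head. The conv → norm → ReLU → pool ordering is the
  conventional one and is pinned so tests are stable.
* **Transformer**: a pointwise convolution lifts the signal to 16 channels;
  one 8-head self-attention block (head width 2) mixes the T tokens; batch
  normalization, temporal averaging (the 16-long descriptor f(2)), an
  affine+ReLU layer, batch normalization again, and the sigmoid head. No
  positional encoding and no residual connections are used — a deliberate
  minimal reading of the architecture; attention then acts as a
  content-based pooling operator.

The engine behind these models is written in the package itself: layer
forward/backward passes in R on BLAS matrix operations, with the
convolution, max-pooling and LSTM inner loops in C++ (the convolution is
evaluated as K shifted GEMMs on pointer-offset subblocks, which avoids
materializing patch matrices). Every backward pass is verified against
central finite differences in the test suite, at layer level and end-to-end.

Batch normalization uses batch statistics (population variance) during
training and accumulated running moments (momentum 0.1, eps 1e-5) at
evaluation, so evaluation-mode forwards are deterministic and accept batch
size 1. Weights initialize uniformly in ±1/sqrt(fan), seeded; builds are
pure functions of (architecture, channels, seed).

## Training and evaluation protocol

`train_config()` defaults are the benchmark recipe: at most 100 epochs,
batch size 32, Adam at a fixed learning rate of 1e-4, 300-step crops.
Each epoch draws fresh crops and augmentation gates. Model selection holds
out a stratified 15% of the training trials (`val_fraction`), scores the
validation cross-entropy after every epoch in evaluation mode, and returns
the parameters with the minimum validation loss. Monitoring the *test* fold
instead would leak; the held-out-validation design is the default. The
validation loss is computed on crops fixed at the start of the run, keeping
the selection criterion deterministic and cheap. The scaler is fitted on all
training-fold trials (including the validation subset) — the validation
split exists for model selection, not as a second test set.

Two cross-validation schemes:

* **Random six-fold** (`random_split()`): within each surgeon, trials are
  shuffled and dealt round-robin from a random starting fold, so every fold
  contains a near-equal number of trials from every surgeon (per-surgeon
  per-fold counts differ by at most 1).
* **LOUO** (`louo_split()`): each fold holds out all trials of one expert
  group and one novice. With 7 experts and 6 novices the two experts with
  the fewest trials are merged and travel together (`auto_merges()`
  generalizes this smallest-groups rule). The expert-novice pairing defaults
  to roster order and is configurable. A leakage check asserts that no
  surgeon appears on both sides of any fold.

Evaluation keeps the original temporal resolution, applies the
training-fitted scaler, thresholds the sigmoid output at 0.5 (the symmetric
default), and tallies TP/TN/FP/FN with Expert as the positive class.
Metrics follow the standard forms — accuracy (TP+TN)/(TP+TN+FP+FN),
precision TP/(TP+FP), recall TP/(TP+FN), F1 2TP/(2TP+FP+FN) — and a metric
with a zero denominator is reported as `NA`, never silently 0; cross-fold
summaries skip `NA` values with a warning. The ± columns of reports are
sample standard deviations (n−1) over folds, pinned for test stability.
One master seed fixes the cohort, the folds, every crop and augmentation
draw, and every initialization, so the entire metric report is bit-for-bit
reproducible.

## Saliency

For the TCN and CLDNN (the two models with a natural final temporal feature
map), `compute_saliency()` extracts the last pre-head activation — the
TCN's F(4) (16 × T) or the CLDNN's last LSTM sequence output (⌊T/4⌋ × 64) —
averages over the feature dimension (the arithmetic mean of the raw
activations; an absolute-value variant is available via `reduce =
"abs_mean"`), min-max normalizes to [0, 1], and linearly interpolates to the
trial's original length. For the TCN the temporal resolution is preserved
end to end, so the interpolation is the identity; the CLDNN's map is
upsampled from quarter resolution. A constant activation map yields all-zero
intensities ("no attention anywhere"), the least misleading rendering of a
degenerate normalization. Min-max normalization makes the track invariant
to affine rescaling of the activations. `render_overlay()` draws the force
trace colored by intensity on a cold-to-warm scale and writes a PNG
deterministically.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run entirely on synthetic
cohorts, at sizes the package chooses for a single-CPU desk run:

* capacity (memorization) checks use 16 perfectly separated 60-step trials
  per architecture, with learning rates chosen per architecture family for
  the check (1e-3 for the recurrent stacks and CLDNN, 1e-2 for the
  batch-normalized TCN and Transformer, whose loss plateaus at 1e-3 within
  the epoch budget);
* the scaled-down benchmark runs TCN and CLDNN on the default 13-surgeon
  cohort with 20 epochs per fold under the random six-fold scheme, and 6
  epochs per fold under LOUO (which is exercised end-to-end with its
  leakage check rather than tuned for accuracy);
* determinism is demonstrated on a 6-surgeon cohort at 2 epochs.

The paper-scale recipe (100 epochs, the full augmentation sweep, the real
glove recordings) is available through the same functions by changing the
configuration.

## Known limitations

* Quantities reported on the synthetic cohort are analogues, not
  reproductions, of results on the deposited glove dataset.
* The Transformer follows the minimal published description (no positional
  encoding, no residuals); richer variants would need additional choices.
* The sampling rate of the sensor is unspecified upstream, so all temporal
  parameters (crop length 300, warp range ⌊T/20⌋, segment length 10) are in
  steps, not seconds.
* Training is single-threaded CPU; at benchmark defaults a six-fold run of
  one architecture on the default cohort takes minutes, not hours, but no
  GPU path exists.
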