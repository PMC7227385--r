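---
title: "Forecasting gait kinematics with gaitcast: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting gait kinematics with gaitcast: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitcast)
```

This vignette is the package's account of what it computes and why the
defaults are what they are. The worked numbers in the README and the values
written by `scripts/acceptance.R` are produced by the code described here;
nothing below asserts a result that the test suite or that script does not
itself compute.

## The forecasting problem

During steady treadmill walking, the kinematics of the thigh and shank are
locked to the stride cycle. The four channels the package models — thigh and
shank linear acceleration along the direction of progression (m/s²) and
thigh and shank angular velocity about the sagittal axis (deg/s) — are what
a pair of body-mounted IMUs would report, and what an assistive-device
controller has available. The task is short-horizon extrapolation: given the
most recent `w_in` samples of all four channels, predict the next `w_out`
samples of all four, and by sliding that prediction across a stride,
reconstruct the whole future trajectory of a gait cycle of a person the
model has never seen.

The supervised transformation is deliberately rigid: the slide between
consecutive windows equals the output size, so the target windows partition
the series. A stride of 170 samples with `w_out = 5` is covered by exactly
34 predicted windows and every sample is predicted exactly once — whole-
stride metrics therefore pool samples, never average overlapping windows.
Trailing samples that do not fill a complete output window are dropped
rather than padded: padding would fabricate data, and the stride/horizon
combinations of interest (170 with 5 or 10) divide evenly anyway.

## The model

The forecaster is a sequence-to-sequence autoencoder:

* **Encoder.** A single LSTM layer consumes the `w_in` x 4 input window and
  keeps only its final hidden state — a fixed-length code summarising the
  recent kinematic context.
* **Adapter.** The code is repeated `w_out` times; the decoder receives the
  same vector at every future step. This is the plain repeat-vector design;
  the alternative of also copying the encoder cell state into the decoder
  buys nothing at these horizons and couples the two layers' sizes.
* **Decoder.** A second LSTM unrolls over the repeated code and returns its
  full output sequence.
* **Head.** One dense layer, applied identically at every step, maps each
  decoder state to the four channels.

Gates use the logistic sigmoid; the cell input and output activations
default to ReLU, with tanh available via `activation = "tanh"`. Training
minimises mean absolute error with Adam (defaults `lr = 0.001`,
`beta1 = 0.9`, `beta2 = 0.999`) on shuffled batches of 100 windows.

Two numerical choices matter here:

* **Gradient clipping** (global norm, default 5). ReLU cell activations
  remove the saturating nonlinearity that normally bounds an LSTM's state,
  so occasional exploding gradients are expected rather than pathological;
  clipping the global norm is the standard remedy and leaves well-scaled
  gradients untouched. Training aborts with the epoch index if the loss
  still becomes non-finite.
* **Initialisation.** Input and dense kernels are Glorot-uniform; recurrent
  kernels are per-gate orthogonal; biases are zero except the forget gate,
  initialised to 1 so memory is retained by default early in training.
  All draws come from R's RNG under the config seed, and batch shuffling
  uses a generator seeded from the same value, so a fit is reproducible
  bit-for-bit on one platform.

The forward pass and backpropagation through time are implemented in
compiled code (RcppArmadillo); the analytic gradients are verified against
central finite differences in the test suite.

### The peephole reference cell

The package also ships a pure-R LSTM memory block with the three
peephole-weighted diagonal connections from the cell state into the input,
forget and output gates — the input and forget gates peep at the *previous*
state, the output gate at the *current* one — with biases fixed at zero.
This cell is deliberately not the production model: peephole connections
are absent from the cell mainstream frameworks (and the production core
here) implement, and the variant is retained as an arithmetic oracle. With
its peephole weights zeroed it must agree with an independently written
standard LSTM loop to 1e-6, which is exactly what the tests assert over
randomly drawn small networks. One presentation quirk is resolved in code:
the output-gate pre-activation is computed as such, even where a source
formula's left-hand side is mislabelled as the cell input.

### Measured-input versus recursive forecasting

Whole-stride forecasts slide over *measured* inputs by default: window `i`'s
input is ground truth, not the model's earlier output. This matches the
evaluation of a recorded test stride with slide = `w_out`, keeps per-window
errors independent of each other, and is the only mode whose per-sample
error profile is interpretable stride-position by stride-position.
`forecast_stride(..., recursive = TRUE)` feeds predictions back instead
(free-run mode); error then compounds and the mode makes no claim beyond
being available.

## Signal conditioning

* **Low-pass filter.** A 2nd-order Butterworth applied forward and backward
  (an effective 4th-order, zero-phase response) with a 15 Hz default
  cut-off — the conventional choice for human-movement kinematics, where
  almost all signal power sits below ~10 Hz and zero phase preserves gait
  event timing. Forward-backward recursion needs care at the ends: the
  implementation extends the signal by odd reflection and starts the filter
  from steady-state initial conditions, so a constant signal passes through
  exactly and edge transients fall on the padding. The realised magnitude
  response is the squared one-pass response of the bilinear-transformed
  design, `1/(1 + (tan(pi f/fs)/tan(pi fc/fs))^4)`, and the tests check
  measured attenuation against that closed form.
* **Normalisation.** Per-feature z-scores with the population (divisor `n`)
  convention — at 10^5 pooled samples the `n` vs `n-1` distinction is far
  below any other error source, and the population form makes fit-then-apply
  exactly idempotent. Parameters are fitted on the training subjects only
  and reused for the held-out subject: fitting them on pooled data would
  leak the test subject's amplitude scale into the model's input
  distribution. A zero-variance feature is an error, named per feature.
* **Differentiation.** Central differences (one-sided at the ends) for
  first derivatives; the second central difference (ends replicated) for
  double differentiation. Both are second-order accurate, stateless and
  match closed forms on polynomials and sinusoids in the tests.

## What the synthetic cohort does and does not emulate

Real multi-subject stride-locked kinematics are available only on request
from their collectors, so the package generates its own cohort with the
statistical structure the pipeline must survive:

* each channel is a sum of `n_harmonics` (default 4) sinusoids at integer
  multiples of the stride frequency — low-order harmonics approximate gait
  kinematics well and make difficulty analytically controllable;
* one multiplicative amplitude factor and one additive phase offset per
  harmonic per channel per subject (SD `subject_variation_sd`, default
  0.08, phase SD `2*pi*0.08` rad) — the leave-one-subject-out challenge in
  two interpretable knobs;
* per-stride duration jitter (SD 0.03 s around a 1.7 s mean at 100 Hz, so
  one stride spans ~170 samples) and additive Gaussian sensor noise
  (default 2% of each channel's amplitude scale).

Defaults describe the study design the package targets: six subjects, 533
strides each, so the five training subjects together contribute 2,665
strides; desk-scale experiments use the same structure with fewer strides.
Amplitude scales default to 2 and 3 m/s² (thigh, shank LA) and 150 and
300 deg/s (thigh, shank AV), magnitudes typical of level walking at
moderate speed. All randomness flows from one root seed through per-subject
derived seeds, so adding a subject never changes earlier subjects' data —
that is what makes the leave-one-subject-out split purely structural.

What the generator does **not** emulate: waveform asymmetries and
double-support transients that are not band-limited to a few harmonics,
within-stride speed fluctuation, correlated (non-white) sensor noise, soft
tissue artefact, and any drift over a 10-minute walk. Passing tests on this
cohort therefore demonstrate that the pipeline's machinery — conditioning,
windowing, training, evaluation — behaves correctly and that the model can
generalise across subject-level amplitude/phase variation; they do not
certify error magnitudes on real motion-capture data, and the package makes
no such claim.

On sampling rate: published descriptions of comparable experiments are
internally inconsistent (100 Hz analysis, 150 Hz capture, horizons quoted in
ms implying ~167 Hz). The rate is therefore an explicit config field
(default 100 Hz) and nothing in the pipeline assumes a particular value.

## Evaluation conventions

Metrics are computed per feature: MAE and MSE in original units (MSE in
*squared* units — m²/s⁴ and deg²/s² — even though comparable tables
elsewhere print MSE with unsquared unit labels), and Pearson correlation,
whose divisor convention cancels. Two scopes are reported: the first
predicted window (`n = w_out` samples) and the whole stride (all windows
pooled, `n` = stride samples covered). A constant series makes the
correlation undefined; `cc()` raises a degenerate-data error rather than
returning 0, so a dead model cannot hide inside a plausible-looking score.

The sweep driver retrains one model per input-window size (default 5 to 40
samples in steps of 5, eight sizes) at fixed `w_out = 5`, one fixed seed
per size by default with optional multi-seed averaging. The horizon driver
fixes `w_in = 25` and compares `w_out = 5` against `w_out = 10` with both
scopes reported. Untrained baselines reuse the exact architecture at its
random initialisation (`epochs = 0`), which keeps baseline and model
comparisons free of architecture confounds.

## Problem sizes

The end-to-end experiments in the test suite and the acceptance script use
six subjects with 30 strides each (five training subjects, ~5,000 windows),
32-unit encoder and decoder, and 20 epochs, replicated over five seeds
where a median is asserted. Those sizes were chosen once as the smallest
cohort on which inter-subject generalisation is a meaningful claim — enough
strides that the model cannot memorise one subject, enough capacity that
the harmonic family is learnable, and small enough that any workstation
reproduces the experiments in minutes. The model-capacity default in
`forecaster_config()` (100 units per layer) reflects published gait-LSTM
practice for full-size datasets and remains fully configurable.

## Known limitations

* The harmonic cohort is easier than real gait; reported errors on it are
  not transferable to motion-capture data.
* Fixed-epoch training with no validation split or early stopping mirrors
  the simplest published recipe; the `epochs` knob is the only guard
  against overfitting.
* Bit-for-bit reproducibility holds per platform/BLAS; across BLAS builds,
  results agree only to floating-point accumulation differences.
* Single-layer encoder and decoder only; stacked or bidirectional variants
  are out of scope.
* The CSV reader infers the sampling rate from the time column's median
  step and does not handle missing samples.
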