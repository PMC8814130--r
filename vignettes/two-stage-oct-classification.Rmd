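---
title: "Two-stage classification of CSC from SD-OCT volumes"
author: "octcsc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage classification of CSC from SD-OCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

Central serous chorioretinopathy (CSC) is a common macular disease in which
serous fluid detaches the neurosensory retina. Management differs sharply
between its two subtypes: acute CSC, marked by subretinal fluid (SRF) that
usually resolves spontaneously, and chronic CSC, marked by retinal pigment
epithelium (RPE) and photoreceptor atrophy that can permanently degrade
vision. Spectral-domain optical coherence tomography (SD-OCT) is the
workhorse modality: a macular volume here is a stack of 25 horizontal
B-scans covering the macula. The task this package addresses is to
classify a whole 25-slice volume into *acute CSC*, *chronic CSC* or
*normal*.

The practical obstacle is that the lesion is visible on only a subset of
the 25 slices (the *lesion cuts*), typically a contiguous central run:
most slices of a diseased eye look normal. An end-to-end volumetric
classifier must discover this structure from raw data, which demands far
more labelled volumes than a typical clinical collection provides.

## The two-stage model

`octcsc` implements a hierarchical system that factorises the decision:

1. **Single-image prediction (SIP).** A convolutional backbone with a
   four-layer fully connected head (dropout after each hidden layer,
   softmax output) maps one preprocessed B-scan to a 3-vector of class
   probabilities $(p_\text{acute}, p_\text{chronic}, p_\text{normal})$.
   Crucially it is trained *only on lesion cuts* of CSC cases (plus the
   slices of normal cases). Non-lesion cuts of CSC eyes look normal; had
   they been labelled acute/chronic during training, the per-slice model
   would be asked to separate visually identical images, and it would
   learn nothing useful.
2. **Final decision (FD).** At test time *all* 25 slices are scored
   (lesion annotations are never consulted), the 25 softmax vectors are
   stacked into a $25 \times 3$ matrix, flattened row-major by slice
   index into a 75-vector, and a multinomial logistic regression predicts
   the case label. Because the features are position-indexed, the FD
   stage can exploit where in the volume the per-slice evidence appears.
   SVM, gradient boosting and random forest are available behind the same
   `fd_spec()` interface; a position-destroying mean-softmax vote
   (`mean_softmax_vote()`) is provided as a sanity baseline.

The FD classifier has 76 parameters per class and trains on a handful of
cases, which is why the system as a whole is data-efficient: the deep
stage sees *slices* (hundreds per cohort), the case-level stage sees a
compact, already-calibrated summary.

`csc_fit()` trains both stages. Following the evaluation protocol, the
training cases are split, stratified by label, 75 % for the SIP stage and
25 % for the FD stage, so the FD classifier is never fitted on softmax
outputs the SIP model produced for its own training patients (which would
be optimistically sharp).

## Preprocessing and augmentation

Raw B-scans (nominally 596 x 1264 px, grayscale rendered as RGB) are
cropped to the retina-bearing 380 x 764 window and downsampled to
163 x 254. The crop origin is configurable and defaults to the centred
window (fovea-centred scans). Downsampling uses exact area averaging:
each output pixel is the mean of the input area it covers, implemented as
a pair of sparse row/column weight matrices. This choice is
anti-aliasing, mass-preserving (constant images stay constant) and has
exactly testable semantics.

Training-time augmentation applies, in a fixed declared order: horizontal
flip with probability 0.5, a multiplicative brightness factor drawn
uniformly from [0.7, 1.3] (clipped to [0, 255]), and rotation drawn
uniformly from [-15°, +15°] about the image centre with bilinear
resampling and black fill in exposed corners. Augmentation runs only on
the training path; the evaluation path is a pure function of the pixels.
Scaled-down presets (`"small"`: 128 x 256 raw, 82 x 155 crop, 35 x 52
input; `"tiny"`: half that again) keep desk-scale experiments cheap while
exercising identical code.

## The network engine

No deep-learning framework is required: the package carries a compact,
fully tested neural-network engine in base R — 2D and 3D convolution via
cached im2col index matrices, max-pooling, per-channel batch
normalisation, adaptive average pooling, dense layers, dropout, an LSTM
with full backpropagation-through-time, and Adam. Every layer's analytic
gradient is verified against central finite differences in the test
suite, which is the load-bearing correctness argument for all training
code.

The default SIP backbone (`"small-cnn"`) is a four-block CNN whose
pooling stages are inserted only while the feature map stays at least as
large as the 2 x 3 adaptive-pooling grid, so small inputs retain coarse
spatial layout. With the default `freeze_backbone = TRUE`, the backbone's
randomly initialised convolutional filters act as a fixed feature
extractor and only the head trains — mirroring the transfer-learning
protocol (frozen pretrained trunk, trainable head) while keeping the
package free of any weight download; random convolutional features are a
well-studied, surprisingly strong representation at this scale. Setting
`freeze_backbone = FALSE` trains the whole network end-to-end through the
same backprop engine. A `"resnet50"` backbone name is reserved for users
who supply pretrained weights; it is deliberately not bundled.

Head widths default to 512-256-64-3 with dropout 0.5, the conventional
decreasing-width reading of "four linear layers with dropouts"; both are
configurable. Optimisation uses Adam (learning rate 1e-3, batch 32 by
default); the training log reports dropout-active loss and accuracy per
epoch.

## Baselines

Two end-to-end comparison models consume the identical preprocessed
inputs:

* **3D-CNN** — three 3D convolution stages with max-pooling, two
  batch-normalisation layers, global average pooling and a softmax
  layer. Filter counts default to small values (8/16/32) and are
  configurable; the reference architecture's channel sizes are not
  treated as normative.
* **CNN-LSTM** — one 2D convolution block of six convolutional layers
  with max-pooling after every second layer, weight-shared across the 25
  slices (`share_weights = FALSE` builds the unshared variant), feeding
  an LSTM with 64 hidden units and a final softmax classifier.

Batch normalisation in the 3D-CNN normalises over the spatial extent of
the current volume during training (training proceeds volume-by-volume
with gradient accumulation) and uses running moments at inference.

## Evaluation protocol

`make_folds()` performs patient-level stratified k-fold assignment:
shuffle within label, deal round-robin, so per-fold label counts are
within one case of the proportional share and no patient ever appears on
both sides of a split. Within each fold's training cases,
`split_sip_fd()` draws the stratified 75/25 SIP/FD sub-split with
largest-remainder rounding (the global SIP count is exactly
`round(0.75 n)`); every label is forced to appear in both stages.
`run_fold()` asserts at runtime that test cases never intersect either
training stage.

`compute_metrics()` reports the confusion matrix (rows = actual,
columns = predicted), accuracy, one-vs-rest sensitivity and specificity
(per class and macro-averaged — the aggregation is a convention we state
explicitly, since a single headline number for a 3-class task requires
one), and Cohen's kappa $(p_o - p_e)/(1 - p_e)$ with expected agreement
from the marginal products. Ties in any argmax resolve to the lowest
class index (acute < chronic < normal). `compare_models()` evaluates
several configurations on one shared fold plan and emits a
models x folds table with an unweighted `Average` column (fold sizes
differ by at most one case under the stratifier).

## The synthetic cohort

The clinical dataset behind the protocol is private, so the package ships
a seeded generator (`generate_dataset()`, `render_slice()`,
`assign_lesion_cuts()`) that emulates its structure: 3 classes, 25
slices per case, and the `"table1"` cohort preset of 82 normal / 109
acute / 106 chronic patients (7425 images, 2050 normal and 5375 CSC).
Each B-scan is a layered retina-like texture — vitreous background, ILM
line, inner and outer bands, RPE line, choroid glow, with gentle foveal
curvature — plus Gaussian noise (default SD 10 gray levels). Lesion cuts
form one contiguous central run whose length is uniform on 5–15 slices,
as real macular lesions span adjacent scans and this gives the FD stage
positional structure to exploit.

The class phenotypes are morphological, not mere brightness shifts: acute
lesion cuts carry a smooth hypo-intense dome (fluid) above the RPE;
chronic lesion cuts carry irregular thinning and darkening of the outer
band and RPE (atrophy). Lesion severity tapers (cosine) from the centre
of the run to its ends, so edge cuts are genuinely subtle and per-slice
accuracy stays below 100 % at the default noise — the regime in which
aggregating 25 slices pays off. All randomness flows through one master
seed with per-case derived streams, making every dataset bit-reproducible.

What the generator does **not** emulate: speckle statistics of real OCT,
choroidal and vascular detail, device- and operator-dependent artefacts,
age/sex covariates, or the visual ambiguity of borderline acute/chronic
cases. Passing tests on this cohort therefore demonstrate that the
pipeline's machinery — slice selection, two-stage training, leakage-free
evaluation — works end-to-end and that its data-efficiency ordering holds
under a controlled signal; they say nothing about clinical accuracy on
real scans, and the clinical headline numbers are deliberately not
treated as reproduction targets.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale problem sizes
chosen as a deliberate design point: cohort arithmetic on the full 297
cases at 32 x 64 px (counts are size-invariant); fivefold CV of the full
pipeline on 60 cases at the `"small"` preset with 20 training epochs; and
the data-efficiency comparison on 18 cases at the same preset, two folds,
three seeded replicates, with short (4-epoch) baseline training — enough
for the easy synthetic signal while keeping a laptop run in minutes. The
clinical-scale geometry (596 x 1264 → 380 x 764 → 163 x 254) is exercised
on single volumes.

These pilot runs train with augmentation disabled. Augmentation exists to
fight overfitting in large trainable networks; with the pilot's frozen
backbone and small synthetic cohorts it instead suppresses the attainable
per-slice accuracy (the brightness jitter in particular dilutes the
hypo-intensity cue of the acute fluid dome at reduced resolution), so the
pilot measures the pipeline at its converged desk-scale operating point.
The augmentation path itself is exercised by its own exact unit tests,
and clinical-scale use would enable it.

Other numerical conventions: softmax rows are validated to sum to 1
within 1e-6; kappa at degenerate expected agreement ($p_e = 1$) is
defined as 1 for perfect agreement and 0 otherwise; the multinomial
logistic FD uses weight decay `1/regularization` (default 1); xgboost and
random-forest FD variants are seeded and single-threaded for
reproducibility; stage seeds are fanned out from the master seed by a
named hashing scheme so no two stages share a stream.

## Known limitations

* The frozen random backbone caps per-slice accuracy below what a
  pretrained trunk would reach on real data; the architecture accepts
  pluggable backbones for that reason.
* `nnet::multinom` fits the FD stage by penalised maximum likelihood;
  with very few FD cases per class the probabilities are strongly
  regularised (this is intended — the stage is designed to train small).
* The pure-R engine is single-threaded and desk-scale; it is not a
  GPU-training path.
* Synthetic phenotypes are stand-ins for the clinical appearance of SRF
  and atrophy and make no claim of clinical fidelity.
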