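---
title: "Methods: a hierarchical multi-view dual-modal MRI classification pipeline on synthetic phantoms"
author: "mvbrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view dual-modal MRI classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvbrain)
```

## Scope and design

`mvbrain` implements, end to end and in base R, a hierarchical multi-view,
dual-modal (structural + functional MRI) classification pipeline for
case-control neuroimaging cohorts, exercised entirely on synthetic brain
phantoms with known ground truth. The package covers:

* a volume data model with canonical RAS orientation, NIfTI and PNG I/O,
  and rigid resampling;
* the phantom generator that stands in for a two-class clinical cohort
  (79 affected / 105 control by default, mirroring the ABIDE I NYU site
  roster);
* structural preprocessing — brain masking, z-score intensity
  normalisation, and rigid registration by mutual-information
  maximisation;
* functional preprocessing — per-frame motion estimation, framewise
  displacement (FD) and frame censoring, ideal band-pass filtering,
  ROI time series, and Pearson/Fisher-z connectivity;
* the multi-plane slice-extraction scheme with subject-level splitting,
  augmentation, and slice accounting;
* a 3D hierarchical convolutional branch (spectral normalisation,
  instance statistics, residual fusion, channel/spatial attention,
  optional graph regularisation, entropy penalty);
* a temporal branch (linear projection, bidirectional LSTM, attention
  pooling, connectivity fusion) and a cross-modality fusion stage;
* training with focal loss and Mixup, standard metrics, ROC/AUC, and
  Grad-CAM saliency.

The fitting surface follows the classic R modelling idiom: `mvb_fit()`
returns an S3 `mvb_model` with `print`, `summary`, `predict` and `plot`
methods. The networks are written with exact hand-coded backward passes
rather than an autodifferentiation framework; every layer's gradient is
checked against central differences in the test suite, which is the main
reason this design is trustworthy despite its simplicity.

## The phantom generator: what it emulates, and what it does not

All empirical claims in this package are made on phantoms, so their
construction matters.

**Structural phantoms** are ellipsoidal "brains" with distinct semi-axes
(0.42, 0.37, 0.32 of the grid — brains are longer than they are wide than
they are tall, and an asymmetric shape is essential for rigid rotations to
be identifiable at all), an interior of intensity 0.5, and a cortical
shell of intensity 1.0. The class effect is morphological: shell thickness
is `1.5 + effect_size` voxels in the affected class versus `1.5` in
controls, with a per-subject jitter (SD `shape_jitter = 0.25` voxels) and
additive white noise (`noise_sd = 0.1`). A bounded smooth texture
(`texture_amp = 0.15`, tanh-clipped) adds anatomy-like spatial structure
while keeping the tissue classes exactly separable at the 0.75 intensity
level, which the generator tests exploit as an analytic oracle.

**Functional phantoms** carry, per atlas ROI, a unit-variance mixture of
three sinusoids drawn inside the 0.01–0.1 Hz passband, a slow 0.002 Hz
drift of amplitude 0.5, and voxelwise white noise. In affected subjects a
designated ROI pair (1, 2) has planted correlation
`rho = min(0.9, effect_size)`; in controls the pair is independent. BOLD
fluctuations are scaled to `bold_amp = 0.05` of the static baseline —
resting-state signal changes are a few percent of baseline, and making
them large would (as it does in reality) corrupt frame-to-frame
registration. Motion is injected by genuinely resampling the affected
frames with the package's own rigid resampler, so motion estimation is a
true inverse problem, not bookkeeping.

Randomness is counter-based: every phantom is a pure function of
`(seed, subject_id, stream)`, so enlarging a cohort never perturbs
existing subjects, and the full pipeline is bit-reproducible.

What the phantoms do **not** emulate: hemodynamic response shapes,
scanner artefacts (bias fields, ghosting, spike noise), realistic
cortical folding, inter-subject anatomical variability beyond shell
thickness, or site effects. A classifier accuracy of 0.9+ on these
phantoms therefore demonstrates that the architecture, gradients,
training loop and evaluation plumbing work and can recover a planted
effect through the full preprocessing chain — it says nothing about
accuracy on clinical data.

## Preprocessing choices

**Brain mask.** Otsu's threshold on a Gaussian-smoothed volume followed by
the largest 6-connected component. The upstream description assumes a
mask exists without defining one; this is the standard cheap construction.

**Z-score normalisation** uses the population (not sample) standard
deviation: the scan is the entire population of its own voxels. Values
outside the mask are zero; a constant-within-mask scan raises an error.

**Registration.** `register_rigid()` maximises the mutual information of
a 32-bin joint histogram over the six rigid parameters by multi-start
coordinate descent with step shrinking at two resolutions (half and
full). Two resolutions, not three: on desk-scale grids (16–32 voxels per
axis) a 4x-downsampled level no longer contains usable rotational
structure and actively misleads the search; `opts$levels` exposes the
ladder for larger images. The result is guaranteed never worse than the
identity initialisation. A `metric = "ssd"` option (negated sum of squared
differences) is provided and is the default for frame-to-frame motion
estimation: realignment is a same-modality problem, for which least
squares is the field standard and histogram MI suffers its classic
interpolation-induced local extrema. Frames are smoothed (sigma = 2
voxels) before motion estimation; smoothing commutes with rigid motion, so
recovery of the injected parameters is unaffected while voxel noise is
strongly suppressed.

**Framewise displacement** is
`FD_t = |d tx| + |d ty| + |d tz| + r (|d rx| + |d ry| + |d rz|)` on
backward first differences of the motion trace, with brain radius
`r = 50` mm converting rotations to millimetres. The censoring threshold
defaults to 0.5 mm (a standard choice; the source text names a threshold
without a value) and is exposed as configuration.

**Band-pass filtering** is an exact ideal filter: the DFT is masked to
`[0.01, 0.1]` Hz inclusive and inverted. This makes the filter idempotent,
exactly energy-preserving in band, and exactly zero out of band (up to
spectral leakage of non-commensurate tones), all of which are tested. The
printed filtering formula omits the imaginary unit and normalisation of
the inverse transform; the implementation is the standard inverse DFT.

**Processing order.** The ROI series is filtered over the full uniform
sampling grid first and censored frames are dropped afterwards, because a
Fourier filter is ill-defined on a gapped series. (ROI averaging and
filtering are both linear, so their order is immaterial.) The per-frame
"slice averaging" step is dimensionally ambiguous in the source
description — averaging the slices of a 3D frame yields a 2D image, not a
"compact 3D representation" — so both readings are provided:
`frame_mean_images()` produces per-frame 2D mean projections for
visualisation, while temporal modelling consumes the ROI time-series
matrix, which preserves the temporal dimension.

**Pearson correlation** is the standard formula (the printed numerator
mixes its subscripts; this is treated as a typo), and the Fisher
transform clips `|r|` at `1 - 1e-7` before `atanh`, with a zero diagonal
by convention.

## Slice extraction and splitting

Slices are taken orthogonal to each anatomical plane (sagittal = x,
coronal = y, axial = z after RAS canonicalisation — the source never
states an axis convention) from a centred window: start index
`floor((D - n) / 2)` for `n > 1`, and the single-slice case uses the
central coordinate `floor(D / 2)` to match the "(x, y, z/2)" description;
the two conventions differ by at most one slice. Slices are resized with
bilinear interpolation in the align-corners convention, under which
resizing to the input size is an exact identity.

The train/test split is at subject level, per class, with
`floor(test_frac * n)` test subjects — the only rounding consistent with
the published 64/15 split of 79 and 84/21 split of 105 at 20% test.
Augmentation (rotation within ±10°, flips at probability 0.5, intensity
scaling in [0.9, 1.1]) draws one parameter set per source volume and
applies it to every slice, preserving inter-slice structure; it refuses
to run on test data.

## Network architectures

**Structural branch.** One shared-weight hierarchical 3D encoder is
applied to each plane's slice stack (an `n x H x W` volume with one
channel); the per-plane pooled embeddings are concatenated in canonical
plane order. The source says the planes are "jointly modeled" without
naming an operator; concatenation of shared-encoder embeddings is the
minimal faithful reading. Each block is: spectrally normalised
convolution (kernel sizes alternate 3 and 5, dilations alternate 1 and 2,
stride 2, channel plan 32-64-128-256 by default) → per-channel
statistical normalisation → ReLU, plus a residual path through a strided
1×1×1 convolution. Channel attention (softmax-projected pooled features;
the printed formula omits the exponential in its denominator, treated as
a typo) and a spatial sigmoid mask follow the last block, then global
average pooling. An optional graph head average-pools the final feature
map into `n_nodes` contiguous blocks along the slice axis, propagates
them by `H' = relu(A H W)` with a chain adjacency, and appends the node
mean to the embedding. The slice stacks live in resized slice space
rather than scanner space, so feature-grid blocks stand in for
atlas-resampled ROIs at desk scale. The embedding entropy
`H(softmax(z))` enters the loss with weight `lambda_ent = 1e-3` (the
source names the term but not its weight).

Spectral normalisation uses five power-iteration steps with persistent
warm-started vectors; in the backward pass the spectral scale is treated
as a constant, the usual practical approximation.

**Functional branch.** The censored, filtered `T x R` ROI matrix is
projected to `d_h` dimensions, encoded by a bidirectional LSTM
(independent parameters per direction, outputs concatenated per step),
pooled by softmax attention over time (the printed attention denominator
is missing its exponential and summation index; a standard softmax is
implemented), and passed through a ReLU transform to `f_seq`. The
Fisher-z connectivity matrix is packed as the row-major upper triangle
excluding the diagonal (no duplicate entries, no infinite diagonal),
projected to the same latent width, and combined as
`[f_seq, f_fc, f_seq * f'_fc]`. The joint representation as printed uses
the *raw* packed vector `f_fc`; `fc_in_concat = "projected"` switches to
the projected one.

**Fusion and head.** Cross-modality fusion reuses the same
interaction-plus-concatenation pattern at the modality level:
`[proj_s, proj_f, proj_s * proj_f]` after projecting both branches to a
common width. Fusion is optional; each branch reports through the same
classifier head — layer normalisation, a 256-unit GELU dense layer,
dropout `p = 0.5` (training only), and a linear map to two logits with
softmax applied only at evaluation. A two-logit softmax head is
implemented as the more specific of the two descriptions in the source
(which also mentions a "sigmoid output" in passing).

## Training and evaluation

Training is seeded minibatch Adam (default learning rate `1e-4`, batch
16 — the source specifies optimisers only for its baselines; the
desk-scale examples in the tests use `1e-3`, appropriate for the much
smaller networks trained there). The focal loss
`-alpha_t (1 - p_t)^gamma log p_t` with `alpha_t = 0.25`, `gamma = 2` is
computed from logits in log-sum-exp form; at `gamma = 0`, `alpha_t = 1`
it reduces exactly to cross-entropy, and it accepts soft targets so that
Mixup (`Beta(0.2, 0.2)` mixing, seeded permutation, labels mixed
identically) can co-occur with it. The per-class weighting reading of
`alpha_t` is noted but the constant form is implemented, matching the
printed scalar. Undefined metric ratios (zero denominators) are reported
as `NaN` with flags, never coerced to 0. AUC is a threshold sweep with
trapezoidal integration; ties count one half, making it exactly the
Mann–Whitney pair statistic. Evaluation reports both sample-level metrics
and subject-level metrics by mean-probability aggregation, since the
source never states which level its figures refer to.

Grad-CAM weights each channel of a chosen encoder block by the spatial
mean of the target-logit gradient, rectifies the weighted activation sum,
and upsamples trilinearly to the input grid.

## Numerical choices and degenerate inputs

* Trilinear/bilinear interpolation everywhere, zero fill outside the
  field of view; integer-voxel shifts are exact, as is resampling of
  affine-linear images.
* PNG export is per-slice min-max scaled to 8 bits; constant slices map
  to zero (division-by-zero guard, stated convention).
* Histogram MI uses equal-width bins over each image's range, no
  smoothing; empty mask overlap is an error.
* `atanh` clipping at `1 - 1e-7`; constant ROI columns raise an error
  naming the ROI; all-zero kernels skip spectral normalisation with a
  warning; zero-variance channels are epsilon-stabilised.
* Ties in coordinate descent are broken toward the incumbent (a step is
  taken only on strict improvement), making registration deterministic.

## Problem sizes

The shipped tests and the acceptance script run at deliberately small
scale, chosen as the smallest sizes at which every effect is still
comfortably detectable: 16–24 voxel grids, 8 slices per plane resized to
16×16, channel plans of 8–16, LSTM width 8, 128–256 time points, and
40 subjects per class for the learning checks (79/105 only for the
accounting checks, which are exact and instantaneous). At these sizes the
complete test suite runs in a few minutes on one core. The architecture
accepts the full-scale configuration (224×224 slices, 32-64-128-256
channels, `d_h = 128`) unchanged, but training it in base R on real
cohorts is not the package's purpose.

## Known limitations

* The networks process one sample at a time; there is no batched tensor
  path and no GPU. This is a verification artefact, not a production
  trainer.
* Spectral normalisation treats its scale as constant in the backward
  pass (exact only at stationarity of the power iteration).
* The graph head's nodes are feature-grid blocks, not anatomical ROIs.
* Motion estimation assumes rigid, frame-wise motion with a mostly
  static background; slice-timing correction, nuisance regression and
  nonlinear registration are out of scope.
* `preprocess_smri()` exposes a bias-field/detrend flag position only as
  a no-op: the source names bias-field correction without defining a
  method, and guessing one would be worse than omitting it.
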