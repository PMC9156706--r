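---
title: "Methods: simulation, models and evaluation in octguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, models and evaluation in octguide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

octguide implements a computer-aided guidance pipeline for epidural needle
placement from forward-view optical coherence tomography (OCT) B-scans: a
synthetic data generator for the five tissue layers traversed during a
puncture, convolutional classifiers arranged as a sequential binary cascade
with a sliding-window switching rule, a needle-to-dura distance regressor
with an analytic surface-detection oracle, a subject-grouped nested
cross-validation/cross-testing harness, and Grad-CAM explanations. This
vignette records the scientific and numerical decisions behind each part.

## The guidance problem

During epidural anesthesia the needle passes, in order, through fat, the
interspinous ligament and the ligamentum flavum before reaching the epidural
space; advancing further punctures the dura and can damage the spinal cord.
A forward-view OCT endoscope in the needle bore produces B-scans (depth x
lateral images of backscattered intensity) of whatever lies in front of the
tip. Two questions matter clinically: *which layer is the tip in now?* and,
once inside the epidural space, *how far away is the dura?*

Rather than one five-way classifier, classification proceeds as four binary
stages matched to the puncture order: (1) fat vs interspinous ligament, (2)
interspinous ligament vs ligamentum flavum, (3) ligamentum flavum vs
epidural space, (4) epidural space vs spinal cord. Each stage's class 1 is
the next-deeper layer, and stage k's class 1 is stage k+1's class 0. The
two tissues a stage must separate are always adjacent layers with strong
local contrast; in particular the globally hardest pair — fat and spinal
cord, which look alike on OCT — is never compared by any stage, which is
why the cascade outperforms a single five-class model.

## Synthetic B-scans

The generator reproduces the qualitative per-class signatures visible in
real scans rather than the physics of interferometric imaging (no wave
optics, no temporally correlated speckle). A frame is built as

    I(z, x) = floor + N(0, floor/4)                        background
            + B exp(-(z - z0)/L) * stripes(z) * h(x) * s   tissue, z >= z0

followed by a separable 3-tap Gaussian blur standing in for the PSF and
quantisation to 8-bit. `B` is the surface brightness, `L` the e-folding
attenuation length in pixels, `stripes` a depth-periodic band pattern
(nonzero only for the interspinous ligament, whose fibre structure produces
transverse stripes), `h(x)` a smooth lateral modulation whose amplitude is
largest for fat (its intensity is visibly less evenly distributed than
spinal cord), and `s` unit-mean multiplicative gamma speckle. The default
parameter table (`default_appearances()`) encodes the observed orderings:
ligament has the longest attenuation length (deepest penetration), the
ligamentum flavum the brightest surface and shallowest penetration, and fat
and cord similar depths but different lateral evenness.

Frames are depth-major (row 1 = shallowest). Classification frames are 181
(X) x 241 (Z) px and regression frames 241 x 681 px, with 6.25 um pixels
in both; the pixel size is stated in the source imaging protocol for the
regression geometry and is assumed equal for the classification crop.
For an epidural-space frame with needle-to-dura distance `d`, the first
`round(d / 6.25)` rows contain only background — the dark gap in front of
the needle — and dura/cord-like tissue begins at that row. Since the
classification depth extent is 241 x 6.25 = 1506 um, classification
datasets draw distances from 200–1400 um by default while regression
datasets use the full 200–2500 um study range (uniformly, the only
distributional statement available being the range).

Subject-to-subject variability is modelled by one log-normal multiplier per
appearance parameter per subject (sdlog 0.05–0.15 depending on the
parameter), shared across that subject's tissues. This is a global
subject effect — e.g. overall brightness or attenuation shifts — chosen so
that subject-grouped validation is non-trivial (a classifier that memorises
absolute intensities of one pig generalises poorly to the next) yet
solvable from class-contrast structure. The per-frame surface row of
non-epidural tissue is jittered uniformly over rows 4–12 so that absolute
surface position alone does not identify a class.

An insertion stream concatenates 100, 700, 100, 100 and 150 frames of the
five layers in puncture order (proportional to the physical layer widths),
with monotonically decreasing distances across the epidural segment. The
`confusable = TRUE` appearance configuration sets the spinal-cord
parameters equal to fat's, making the fat/cord pair statistically
indistinguishable — the failure mode that motivates the cascade — while
leaving every adjacent-stage contrast intact.

What passing tests on these data do *not* show: robustness to real-tissue
texture, to compression artefacts, to needle contact effects, or to
distribution shifts beyond global intensity scaling. The simulator's role
is to make the pipeline's logic and learning machinery testable end to end,
at desk scale, with known ground truth.

## Networks and training

No GPU deep-learning stack is assumed: the package contains its own small
convolutional engine, written as im2col patch extraction plus BLAS matrix
multiplies, with exact backpropagation (verified against finite differences
in the test suite). Architectures are stacks of 3x3-conv / ReLU / 2x2
pooling blocks: `small-cnn` (8, 16 filters), `resnet50-like` (12, 24),
`inception-like` (12, 24, 48) and `xception-like` (6, 12) are
capacity-keyed stand-ins, not reimplementations of the eponymous
backbones; `small-cnn` is the classifier default and the deeper
`inception-like` the regression default (two-block nets underfit the
681-px-deep regression geometry). Classifiers
end in global average pooling and a dense softmax layer — the head used by
the full-size image backbones, and the architecture for which Grad-CAM's
channel-weighting is exact. The regressor ends in a flatten and a single
dense unit with identity activation, because the distance signal is the
*position* of the dura surface, which global pooling would discard.

Inputs are block-mean downsampled (factor 8 x 8 for classification frames,
4 in depth x 8 laterally for regression, keeping depth resolution where the
signal lives). Classifier inputs are centred by the scalar training-set
mean pixel value (stored on the model and reapplied at prediction) and
scaled by 1/255. Regressor inputs are standardised per frame (zero mean,
unit SD per image): the acquisition's own per-image 0--255 scaling leaves a
residual gain that depends on the brightest speckle grain, and through it
on subject-level speckle and attenuation multipliers; with a linear
distance readout that gain becomes a proportional per-subject distance
bias, which per-frame standardisation removes. The regression family also
uses average
pooling rather than max pooling — max pooling propagates the brightest
speckle grain and destroys the sub-cell surface-position interpolation the
distance readout relies on, while averaging is the natural denoising
operation for speckle imagery. Classifiers keep max pooling.

Optimisation follows the published recipe exactly: SGD with Nesterov
momentum, learning rate 0.01, momentum 0.9, decay 0.01, batch size 32;
sparse categorical cross-entropy for classification with early stopping at
patience 10; 20 epochs for regression. Decisions the recipe leaves open,
resolved here:

* **Decay** is applied as the per-epoch schedule `lr / (1 + decay * epoch)`,
  configurable.
* **Early stopping** counts an epoch as improving only if validation loss
  drops by at least `min_delta = 1e-4`; on near-separable synthetic tasks
  the loss otherwise decays asymptotically and the patience rule would
  never fire. Best-epoch weights are retained regardless. The epoch cap is
  100.
* **Regression loss.** Only the evaluation metrics (MAPE, MAE) are stated,
  not the training loss; MAPE itself is used as the objective, evaluated on
  fraction scale (mean relative absolute error — the same minimiser as the
  percent scale). At percent scale the gradients are 100x larger and SGD at
  the fixed learning rate oscillates until the ReLUs die, collapsing the
  network to a constant output; the fraction scale is the numerically sane
  formulation of the same objective. Internally targets are expressed in
  millimetres and predictions converted back to um.
* **Output bias initialisation.** The regression head's bias starts at the
  training-mean distance, so the 20 fixed epochs are spent learning the
  image-dependent signal rather than walking the bias to the target scale.
* No pretrained weights; He initialisation from a seeded RNG. Training is
  bit-reproducible given a seed, and predictions are invariant to how
  frames are batched.

## The cascade state machine

The stream logic annotates each incoming frame with three pieces of
information: the fraction of the last 50 frames predicted as class 1 (while
fewer than 50 frames have been seen in the stage, the denominator is that
count), the active classifier, and the truth/predicted labels. The fraction
is coloured like a traffic light: green below 26 class-1 predictions,
yellow from 26, red at 35. When the class-1 count reaches 35 the needle is
deemed to have entered the deeper layer and the next classifier activates;
stage 4 (epidural vs cord) is terminal, and no fraction or zone is shown
once it is active.

Two details the display rule leaves open are fixed as follows. The window
is cleared on a switch (the new classifier's predictions are not
commensurable with the old window's; configurable off), and a switch may
fire before 50 frames have accumulated — 35 of fewer than 50 is a stricter
condition, so this is conservative. Predictions feeding the window are hard
argmax labels. With truth-oracle predictions on the default 1150-frame
stream, switches land at frames 135, 835 and 935 (each 35 frames after a
boundary), a closed-form check kept in the tests against an independent
recount-every-frame reference.

## Nested evaluation

Subjects, not frames, are the sampling unit: all frames of a subject stay
on one side of every split. The outer loop rotates each of the 8 subjects
through the test role; within an outer fold the inner loop rotates each of
the 7 remaining subjects through validation (6 train / 1 validation),
giving 56 train/validation/test triples. Candidate architectures are
compared by their mean inner-fold validation metric (accuracy for
classification, MAPE for regression; ties broken by input order), the
winner is retrained on all 7 cross-validation subjects and evaluated once
on the held-out test subject, and test metrics are aggregated as mean ±
standard error (sample SD / sqrt(folds); a single fold reports SE 0,
flagged). Because no validation subject remains at retraining time,
classification retraining runs a fixed budget equal to the rounded mean
best epoch of the winner's inner runs; regression retraining keeps its
fixed 20 epochs. An automated audit asserts subject-disjointness before
every training run and aborts on any leakage. Per-run seeds derive
deterministically from (fold, architecture, rotation).

## Surface detection and Grad-CAM

The analytic distance oracle averages intensity per depth row, estimates
the background from the darkest rows (5% quantile), requires a minimum
background-to-peak contrast of 25 intensity units (otherwise "no surface
found"), and places the dura surface at the first row exceeding background
plus 40% of the contrast; the distance is (row - 1) x 6.25 um. On
generated frames this inverts the generator to within one pixel for over
99% of frames, which is what makes it usable both as a labelling oracle
and as a non-learned baseline.

Grad-CAM heatmaps are computed at the deepest convolutional layer: the
gradient of the target class's pre-softmax score with respect to the
ReLU'd feature maps is spatially averaged into channel weights, the
weighted map sum is rectified, bilinearly upsampled to the frame grid and
max-normalised to [0, 1]; an identically zero gradient yields an all-zero
map. With the global-average-pooling head this channel weighting is exact
rather than approximate.

A known limitation: on stage-3 epidural frames the compact networks'
saliency concentrates at the *dura surface* rather than filling the dark
gap above it. In this generative family the ligamentum flavum — the
shallowest-penetration layer — actually contains *more* total dark area
per frame than an epidural frame does, so bare darkness is flavum
evidence; "darkness above the first tissue" is only expressible with
full-frame receptive fields and absolute-position awareness, which the
desk-scale engines cannot form (this was verified across both heads, two
and three conv blocks, an auxiliary depth-coordinate channel, and both
raw-logit and logit-difference targets). The gap-band mean consequently
exceeds the outside mean only for the shorter gaps.
The surface the models attend to is the physically meaningful boundary,
but the package does not reproduce, at this scale, the full-size-network
behaviour of highlighting the black space itself.

## Problem sizes and limitations

The package's own studies (tests and the acceptance script) run, per task:
8 subjects x 200 frames/class for stage classification, 8 x 300 epidural
frames for regression, 4 subjects x 120 frames/class for the
cascade-vs-multiclass comparison under the confusable configuration, and
the 1150-frame default insertion stream. These sizes were chosen as the
smallest at which subject-grouped generalisation is meaningfully exercised
on a single CPU; the acquisition-scale default (1000 frames per layer per
subject) remains the generator default.

Known limitations: the simulator does not model real porcine image
statistics beyond the named qualitative features; architectures are
desk-scale; the regression loss choice, its input normalisation and the
classification epoch cap are assumptions where the published recipe is
silent; Grad-CAM gap saliency holds only for shorter gaps (above); and
"standard error" follows the sample-SD/sqrt(n) convention, which the
source tables do not spell out.
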