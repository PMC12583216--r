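---
title: "Automated Kauppila AAC scoring: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated Kauppila AAC scoring: models, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Abdominal aortic calcification (AAC) visible on lateral lumbar radiographs
is an established radiological marker of atherosclerosis and cardiovascular
risk. The reference grading scheme is the Kauppila AAC-24 score: the
abdominal aorta in front of vertebrae L1-L4 is divided into four segments
(bounded by the midpoints of the adjacent intervertebral spaces), each
segment's anterior and posterior wall is graded 0-3 by the craniocaudal
length of calcified plaque relative to the segment length, and the eight
grades are summed to a 0-24 total. Totals of 0-4 are read as no or mild
AAC, 5-15 as moderate, and 16-24 as severe.

`aacquant` implements a fully automated two-stage scoring pipeline:

1. a convolutional encoder-decoder segments vertebral bodies L1-L5;
2. an anatomy-driven crop around the lumbar spine and prevertebral soft
   tissue is resized and fed to a residual convolutional network with
   spatial and channel squeeze-and-excitation (SCse) attention that
   regresses the continuous AAC total,

together with the Kauppila engine itself, an evaluation suite (MAE, MSE,
Spearman correlation, R^2, bootstrap confidence intervals, ICC(2,1),
weighted kappa, severity-stratified classification metrics), a
gradient-weighted class-activation mapping explainer, and a synthetic
phantom generator that provides labelled data for every stage.

## The Kauppila engine

`grade_segment()` encodes the grading rule literally: 0 for no detectable
calcification, 1 for a calcified length fraction strictly below 1/3, 2 for
a fraction of at least 1/3 and at most 2/3, and 3 above 2/3. Both
boundaries therefore grade 2. Any nonzero calcification scores at least 1.

`segment_spans()` derives the four segment row intervals from a vertebra
label mask: the L1 segment starts at L1's superior extent, interior
boundaries sit at the integer midpoint of each intervertebral gap, and the
L4 segment ends at the midpoint of the L4-L5 gap. Pixels are assigned to
the span containing their row; how human raters resolve plaque overlying a
boundary row is not standardised, and this convention makes the choice
explicit and reproducible.

`score_from_masks()` is the package's reference ("oracle") scorer. The
calcified length fraction of a (level, wall) segment is measured as the
number of distinct image rows in the span that contain calcified pixels
assigned to that wall, divided by the span length - a projection onto the
craniocaudal axis, which matches the length semantics of the grading rule
and is insensitive to plaque thickness; scattered deposits count by the
union of covered rows. Wall assignment splits calcified pixels at a single
vertical midline through the aortic band. By default the midline is
estimated as the midpoint of the calcification-bearing column range, which
is exact whenever both walls carry plaque; an explicit midline can be
passed when the aortic geometry is known (the phantom consistency checks
do this, since a single-wall case gives the estimator no information about
where the band midline lies).

## The phantom generator

No public radiograph collection accompanies the scoring system, so the
package generates its own study data. A phantom is a portrait-format
grayscale image with five rectangular vertebral bodies (row 0 superior),
intervertebral gaps, a faint anterior aortic band at a fixed offset from
the anterior vertebral margin, and per-segment calcified wall deposits
rendered as contiguous high-intensity strips whose row extent realises a
requested length fraction. The rendered strip length is chosen as the
rounding of `fraction * span` that preserves the analytic grade, so
rasterisation cannot flip a grade at the 1/3 and 2/3 boundaries; the
ground-truth score attached to each phantom is computed analytically from
the requested fractions, and the mask-based scorer recovers it exactly on
generated cohorts (the suite checks >= 95% exact and 100% within +/- 1 over
500 phantoms).

Cohort sampling draws a severity category from a configurable mix
(default 387 : 1124 : 226, about 22% / 65% / 13% no-mild / moderate /
severe, the near-normal severity distribution of a large multicenter
training cohort), then a target total uniformly within the category, then
eight grades summing to that total, then fractions within each grade's
interval (kept 0.03 away from the grade boundaries so that the rendered
strip is unambiguous). Simulated "centers" are photometric strata only:
per-case brightness offset, contrast scale and noise level are drawn from
configurable ranges, and vertebral geometry is jittered by +/- 12%.
Intensity ordering is bone > calcification > soft tissue by default; the
grading rules are geometric, so the exact radiometry only needs to make
calcification separable.

What the phantoms deliberately do not model: beam hardening, scatter, 3D
projection, vertebral pathology, and realistic plaque morphology (deposits
are contiguous strips, not punctate or arc-shaped lesions - a stand-in
choice, since no morphology statistics are published for the scoring
system). Passing the recovery criteria on phantoms therefore demonstrates
that the pipeline's machinery is correct and trainable, not that the
trained weights transfer to clinical radiographs.

## Segmentation

The segmenter is a U-shaped encoder-decoder built on the package's own
convolution engine: per level, two 3x3 convolution + instance
normalisation + ReLU pairs; 2x2 max pooling between encoder levels;
nearest-neighbour upsampling with a 1x1 channel projection and a single
3x3 fusion convolution per decoder level (a lean decoder - phantom
anatomy does not need a symmetric one); a 1x1 head produces six class
maps (background + L1..L5). The input has two channels: the Z-scored
image and a normalised row coordinate. The coordinate channel gives the
otherwise translation-equivariant network the craniocaudal position cue
required to distinguish otherwise identical vertebrae - at desk scale the
receptive field alone cannot reliably count vertebrae from the image top.

Training minimises the equally weighted mean of a soft-dice loss and
cross-entropy with Adam (learning rate 3e-3). The desk-scale default is
depth 4 with channels 16-32-64-128 on 128 x 256 phantoms, batch 4,
4 epochs - about five minutes on one CPU, reaching mean held-out Dice
around 0.99 (the suite asserts >= 0.85, a margin over seed-to-seed
variation). A `preset = "full"` configuration mirrors a radiograph-scale
setting (9 levels, channels up to 512, 1536 x 1024 patches, batch 2,
five-fold cross-validation with score-mean ensembling before the argmax)
but is not exercised by the tests. Prediction keeps, per label, only the
largest connected component.

`check_roi_coverage()` is the quality gate before ROI extraction: all five
labels present, one component each, centroid ordering superior to
inferior, and each vertebral height within 0.3-3 times the median. The
thresholds are package-defined (no published criteria exist to copy) and
config-exposed.

## ROI extraction

The crop runs vertically from the estimated inferior border of T12 to the
inferior border of L5. T12 itself is never segmented, so its inferior
border is estimated as L1's superior extent minus half the mean
intervertebral gap - anatomically the T12-L1 gap resembles the lumbar
gaps; the fraction is an argument. Horizontally the crop spans the
vertebrae and extends 0.75 x the mean anteroposterior vertebral length
anteriorly to include the prevertebral soft tissue carrying the aorta.
All bounds clamp to the image. The crop is Z-score normalised (a
zero-variance crop maps to zeros) and then resized with bilinear
interpolation; normalising before resizing is a recorded choice (the
alternative order differs only through interpolation rounding) and the
normalisation record travels with the patch. The radiograph-scale target
is 1000 x 500; the desk-scale phantoms use 250 x 125.

## Score regression

The regressor is a residual network: a stride-2 3x3 stem with 2x2 max
pooling (the classic 4x stem downsampling), then stages of residual
blocks (3x3 conv - instance norm - ReLU - 3x3 conv - instance norm, plus
a projected skip where shape changes), an SCse attention module after
each residual block - the channel branch gates channels via a two-layer
bottleneck on globally pooled features, the spatial branch gates pixels
via a sigmoid 1x1 convolution, and the two gated maps are summed - global
average pooling, and a batch-norm / dropout (p = 0.5) / linear head with
one continuous output. The desk default is three stages of two blocks at
8-16-32 channels on 250 x 125 inputs; `preset = "full"` selects the
34-layer layout (stages 3-4-6-3, channels 64-512) on 1000 x 500 inputs.
Instance normalisation is used inside blocks so that training is exact at
any batch size; the head uses true batch statistics with running averages
for inference. The head bias is initialised to the training-score mean so
early iterations refine structure rather than the output offset. Models
train from scratch; no pretrained weights are downloaded or bundled,
though `regressor_config(init_params = )` accepts a compatible model's
parameter tree as a warm start.

Optimisation uses SGD with momentum 0.9 and
weight decay 5e-4, mean-squared-error loss, base learning rate 0.01
reached by a 200-iteration linear warmup from 0.01/3 and then cosine
decay to 1e-4 over the remaining iterations (`lr_at()` is parameterised
per iteration; "remaining training" is ambiguous at iteration granularity
and the per-iteration reading makes the schedule exact at every step).
Validation loss is monitored every `val_check_every` epochs (default 10)
with early stopping after `patience` checks without improvement (the
default of 5 is a package choice - no standard patience exists for this
recipe - and it is exposed in the configuration); the best-validation
parameters are kept.

The augmentation suite - brightness +/-10%, contrast +/-10%, Gaussian
noise with sigma drawn from [0, 10] on a 0-255 intensity scale (rescaled
to the patch's own range, since patches are Z-scored), shift +/-5%,
scale +/-5%, rotation +/-30 degrees, applied in that fixed order to the
training set before each epoch - is implemented and tested. The
desk-scale training recipe leaves it disabled: the cohort generator
already injects photometric heterogeneity, and at a 12-epoch budget the
extra sampling noise slows convergence without a generalisation benefit
on phantoms. Scores are never altered by augmentation.

The desk-scale run (400 training patches, 60 validation, 60 held-out,
batch 16, 12 epochs, 100-iteration warmup) takes roughly ten minutes on
one CPU and recovers synthetic truth with Spearman rho about 0.87 and MAE
about 2.2; the suite asserts rho >= 0.8 and MAE <= 2.5, documented
stochastic tolerances at the fixed seeds used by the fixtures.

For categorical analyses, continuous predictions are clamped to [0, 24]
and rounded half-to-even before severity classification; raw continuous
values enter MAE/MSE/rho/R^2 and ICC, while kappa uses the categorised
pathway. Both choices are recorded in the evaluation report.

## Evaluation statistics

`icc_2_1()` computes the two-way random-effects, single-measure,
absolute-agreement intraclass correlation directly from the ANOVA mean
squares; the tests cross-check it against an independent `aov()`
decomposition. `weighted_kappa()` defaults to quadratic disagreement
weights with linear selectable (no scheme is standard for AAC totals; the
report always records the scheme used). Bootstrap confidence intervals
are empirical 2.5/97.5 percentiles over B replicates; `mode = "resample"`
bootstraps test-set pairs, and `mode = "retrain"` reproduces the full
procedure of resampling the training set with replacement and retraining
(B = 1000 is the conventional choice; the desk default is smaller).
Proportion intervals use the Wilson score method, chosen because it
behaves sensibly at the extreme proportions that severity subgroups
produce. Degenerate inputs (zero-variance references, categories absent
from both raters, empty segments) are flagged as undefined rather than
imputed.

## Explanation

`grad_cam()` backpropagates the scalar output to a chosen backbone block,
averages the gradients spatially into per-channel weights, forms the
rectified weighted activation sum, upsamples bilinearly and
max-normalises. `focus_fraction()` quantifies focus correctness as the
fraction of the top-decile heatmap pixels lying inside the (optionally
dilated) calcification mask mapped through the same crop and resize as
the patch. This is a declared computable proxy for the radiologist
judgment of "correct focus" used in reader studies - no claim is made to
reproduce any reader-study percentage.

The default target is the last convolutional block, the common practice
for activation mapping. At desk scale that block is spatially very
coarse (16 x 8 before upsampling), so for quantitative localisation the
suite probes an early stage-1 block (62 x 31), where the trained model's
top-decile activations cover calcified regions at several times the
chance level set by the mask's area fraction. Heatmaps should be read as
regional attention evidence, not lesion segmentations.

## Numerical and design notes

* All gradients in the network engine are analytic and validated against
  central finite differences (relative error around 1e-10) in the suite.
* Coordinates are 0-based with half-open boxes throughout; row 0 is
  superior. Gap midpoints round toward the superior side.
* Calcification strips start at the segment's superior boundary by
  default (`random_strip_position` randomises the offset); grades depend
  only on length fraction, so truth is unaffected.
* Phantom images round-trip disk as 16-bit TIFF; masks as 8-bit label
  PNG; manifests as CSV with columns
  `id, g_L1a..g_L4p, total, category, seed`.
* All randomness flows from explicit seeds; phantom rendering uses an
  isolated RNG stream so generation never perturbs the caller's RNG
  state. Pipeline stages derive their seeds from the global seed.
* Problem sizes in the test suite (60-phantom segmentation, 400-patch
  regression, 500-phantom consistency) are the package's desk-scale
  study conditions: large enough for stable recovery statistics, small
  enough that the full suite trains both networks from scratch on one
  CPU.

## Known limitations

* The strip-shaped calcification model understates the difficulty of
  real plaque morphology; recovery metrics on phantoms are upper bounds
  on clinical performance.
* The wall-assignment midline is a projection heuristic; strongly oblique
  aortas would need an explicit midline or a curved centerline model.
* The segmentation coverage criteria are package-defined stand-ins.
* `preset = "full"` configurations are provided for completeness but are
  not trained in the test suite.
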