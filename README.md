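# aacquant

Automated scoring of abdominal aortic calcification (AAC) on lateral
lumbar radiographs, for researchers studying vascular calcification as a
cardiovascular risk marker and for method developers who need a fully
testable, self-contained reference implementation.

## What it does

The Kauppila AAC-24 score grades calcified plaque in the abdominal aorta
in front of vertebrae L1–L4. Each of the four aortic segments (bounded by
the midpoints of adjacent intervertebral spaces) is graded separately on
its anterior and posterior wall by the craniocaudal calcified length
fraction *f* of the segment:

```
grade = 0  if f = 0          (no detectable calcification)
        1  if 0 < f < 1/3
        2  if 1/3 <= f <= 2/3
        3  if f > 2/3
```

The eight grades sum to a total in 0–24, tiered as no/mild (0–4),
moderate (5–15) or severe (16–24) AAC.

`aacquant` implements the full automated pipeline around this score:

* **kauppila** — the scoring engine: per-segment grading, totals,
  severity tiers, segment geometry from vertebra masks, and an exact
  mask-based reference scorer (`score_from_masks`).
* **phantom** — a synthetic radiograph generator with known vertebral
  anatomy and per-segment calcification of controlled length fraction,
  plus multicenter-style photometric heterogeneity; every phantom carries
  its analytic ground-truth score.
* **segmentation** — a trainable encoder–decoder convolutional network
  labelling L1–L5 (combined soft-dice + cross-entropy loss), with mask
  quality control.
* **roi** — the anatomical crop (inferior T12 border to inferior L5
  border, 3/4 mean AP vertebral length of anterior soft tissue), Z-score
  normalisation and bilinear resize.
* **regression** — a residual convolutional network with spatial and
  channel squeeze-and-excitation attention regressing the continuous
  score; SGD with momentum under a linear-warmup + cosine-decay schedule,
  early stopping, and the photometric/geometric augmentation suite.
* **evaluation** — MAE, MSE, Spearman ρ, R², bootstrap CIs, ICC(2,1),
  weighted kappa, clinical-acceptability proportion (|error| < 4), and
  severity-stratified accuracy/sensitivity/specificity/NPV/PPV with
  Wilson CIs.
* **explain** — gradient-weighted class-activation heatmaps and a
  quantitative focus-correctness score against calcification masks.

The convolutional network engine itself (im2col convolutions, instance
normalisation, attention, SGD/Adam) is part of the package (R + Rcpp) and
is finite-difference validated in the test suite.

## Worked example

```r
library(aacquant)

# a phantom with a half-length deposit on L1's anterior wall and a
# 90%-length deposit on L3's posterior wall
spec <- phantom_spec(calcified_fractions = c(0.5, 0, 0, 0, 0, 0.9, 0, 0))
s <- make_phantom(spec, seed = 3)
s$truth
#> Kauppila AAC-24 score
#>           L1 L2 L3 L4
#> anterior   2  0  0  0
#> posterior  0  0  3  0
#> total: 5  category: moderate

# the mask-based reference scorer recovers the truth from pixels alone
score_from_masks(s$calcification_mask, s$vertebra_mask)$total
#> [1] 5

# grading rules and tiers directly
grade_segment(c(0.2, 0.5, 0.8))
#> [1] 1 2 3
classify_severity(c(4, 9, 16))
#> [1] no_mild  moderate severe
#> Levels: no_mild moderate severe

# end-to-end: simulate cohorts, train both networks, evaluate, explain
res <- run_pipeline(run_config(n_train = 60, n_val = 20, n_test = 20,
                               seed = 1))
res$report         # MAE, MSE, rho, R2, ICC, kappa, severity table
```

A demo-scale `run_pipeline()` trains the segmenter (four epochs, ~5 min)
and the regressor (~10 min) on one CPU and writes the evaluation report,
the test-set manifest and a heatmap overlay under `output_dir`.

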