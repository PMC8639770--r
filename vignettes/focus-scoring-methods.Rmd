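---
title: "Scoring transformed foci in the Bhas 42 CTA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring transformed foci in the Bhas 42 CTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scoring problem

In the Bhas 42 cell transformation assay (CTA), cells carrying the v-Ha-ras
oncogene form a contact-inhibited monolayer; exposure to a tumour promoter
lets transformed cells escape inhibition and pile up into *transformed
foci*. After Giemsa staining, candidate regions are photographed and scored
by experts against six morphological criteria: basophilic (dark, saturated
staining), spindle-shaped cells, multilayered growth, random cell
orientation, invasive borders, and at least 100 cells. The per-well focus
counts across a concentration ladder then drive the assay-level decision:
a chemical shows promotion activity when the focus frequency is increased
significantly at two consecutive tested concentrations.

focusCTA implements this scoring pipeline twice — a classical branch built
on hand-crafted features and logistic regression, and a CNN branch built on
an 18-layer residual network — together with the evaluation machinery and
the promotion call, plus a synthetic image generator that makes the whole
chain testable without micrograph data.

## The synthetic generator

`sample_phenotype()` draws the morphological parameters of one focus
candidate; `render_image()` rasterizes it. The generator is *not* a
photorealistic simulator. It emulates exactly the image properties the
downstream operations consume:

* a light, low-saturation background with smoothed noise (a stained
  monolayer at low magnification);
* a central cluster region bounded by `r(theta) = R (1 + f(theta))`, where
  `f` is a random low/mid-frequency Fourier series whose amplitude scales
  with `border_irregularity`; at irregularity 0 the cluster is an exact
  disk, and the measured excess perimeter grows monotonically with the
  parameter (about 5% at 0.05 and 20-50% over the positive range 0.5-0.9);
* a basophilic tint over the cluster and individual anti-aliased elliptical
  "cells" in a jittered Giemsa blue-purple; both darken with
  `stain_intensity`, so the median grayscale (MD) of the segmented region
  decreases in the stain parameter;
* cluster radius derived from `cell_count` and areal `density`
  (`R = sqrt(n / (pi d))`), so the 100-cell criterion maps onto region size
  (ED); the `micro-focus` style (small dense foci, as induced by
  1-nitropyrene) uses higher density and lower counts, `LCA-like` larger
  and darker foci.

Positives satisfy all six criteria. Negatives are sampled from the positive
distribution and then violate **one** randomly chosen criterion among cell
count, stain intensity and border irregularity; the violated criterion is
recorded so that each hand-crafted feature can be ablated. A `contrast`
dial in `[0, 1]` interpolates the violated parameter between its fully
benign range (contrast 1, the default and the setting used by the tests)
and the positive distribution (contrast 0, in which labels carry no
signal). Because class separation is generated along exactly the three
feature axes the classical branch measures, a high AUC on synthetic data
demonstrates that the pipeline recovers planted structure — it says nothing
about performance on real micrographs, where the criteria are correlated,
partially violated, and embedded in far richer texture.

Every operation is a pure function of its arguments including the seed;
datasets, images and manifests are bit-reproducible.

## Classical branch

`segment_focus()` converts the image to HSV, quantizes saturation to
0..255, and thresholds it by discriminant analysis (Otsu's method):
`otsu_threshold()` maximizes the between-class variance of the split
`{<= t} / {> t}`, breaking ties toward the lowest index. Foreground is the
high-saturation side (the stained, dense cells); a config switch flips the
polarity. Since each micrograph frames one candidate, the focus region is
the largest 8-connected foreground component. Images whose saturation
histogram is single-valued, or that segment to nothing (faint negatives),
receive a flagged fallback feature vector (background median, ED = WPD = 0)
so batch runs never abort.

From the region, `compute_features()` derives

* **MD** — median of the Rec. 601 luma over the region;
* **ED** — equivalent diameter `sqrt(4 AREA / pi)`;
* **WPD** — `(FRP - EFP) * (AREA - AREA_min) / (AREA_max - AREA_min)`,
  the excess of the measured region perimeter (FRP) over the equal-area
  circle's perimeter (EFP = pi ED), weighted by the min-max-normalized
  area, with `AREA_min`/`AREA_max` taken over the training regions
  (`fit_scaler()`).

Numerical choices the definitions leave open: the perimeter estimator is
the weighted boundary-configuration count used by standard regionprops
implementations (straight, diagonal and corner boundary elements weighted
1, sqrt(2), (1+sqrt(2))/2), which is within 5% of the truth on axis-aligned
squares and within 6% of EFP on rasterized disks; the WPD area weight is
clamped to [0, 1] when a test region falls outside the training extremes
and defined as 0 for a degenerate scaler; pixel coordinates are row-major
with the origin at the top-left.

`fit_logistic()` standardizes the three features (their scales are
incommensurate) and fits by Newton-Raphson with a tiny ridge
(lambda = 1e-6) on the slopes, which stabilizes separable fixtures while
perturbing coefficients negligibly; the tests require agreement with a
generic optimizer of the same penalized likelihood to 1e-4. Decisions use
threshold 0.5, matching the CNN branch.

## CNN branch

`build_model()` constructs the standard 18-layer residual network (7x7/2
stem, 3x3/2 max pool, four stages of two basic blocks at 64/128/256/512
channels, global average pooling) with a single-logit head, 11,177,025
parameters, trained from scratch — no pretrained weights are used. The
engine is written in the package itself (im2col + GEMM convolutions, batch
normalization, analytic backward passes, with two small compiled kernels
for the optimizer update and the col2im scatter), which keeps training
bit-reproducible given the seed.

The training protocol (`train_config()` defaults): resize to 224x224,
augment with rotation uniform in [-90, 90] degrees, translation in
[-44, 44] px, shear in [-15, 15] degrees and horizontal/vertical flips at
probability 0.5; binary cross-entropy on the sigmoid logit; Adam at initial
learning rate 1e-4 decayed by cosine annealing to 0 across the epochs
(endpoints: `lr(0) = lr_init`, `lr(last) = lr_min`); minibatch 32;
50 epochs; the reported checkpoint is the parameter state at maximal
validation accuracy (earliest epoch on ties); `run_trials()` repeats
training over seeds (5 in the full protocol) and reports mean and sample
SD of each test metric.

Choices the protocol leaves open, fixed here: images are resized first and
augmented at the input size (the +/-44 px translation is ~20% of 224,
consistent with post-resize translation); the affine fill colour is the
per-image border median (no black corners, which nothing in a Giemsa
micrograph resembles); inputs are scaled to [0,1] then normalized with
mean 0.5 / SD 0.5 (no pretraining, hence no ImageNet statistics); one
master seed per trial drives initialization, shuffling and augmentation;
batches of size 1 are skipped (batch statistics are undefined).

### Problem sizes used by the tests

The package's correctness checks train at a reduced scale chosen so the
network still has to learn the planted structure: 150 + 150 synthetic
images, split 160/40/100 (stratified), input 32x32 with translation
+/-6 px (the same 20% ratio), minibatch 32, 10 epochs, learning rate 1e-3
for the short schedule, seeds 1-3. Under these conditions the mean test
AUC across seeds exceeds 0.9 (typically ~0.97), and training on
label-permuted data stays within [0.35, 0.65] for every seed. The full
224x224 / 50-epoch / 5-seed protocol is available unchanged through
`train_config()`.

## Evaluation and the promotion call

`stratified_split()` shuffles within class and allocates by largest-
remainder rounding, so each split's class ratio is preserved within one
sample; 70/10/20 reproduces the main protocol, 90/10 plus an external test
manifest the transfer protocol (`run_trials(test_manifest = ...)` asserts
id-disjointness). `confusion_at_threshold()` predicts positive at
score >= threshold. `roc_auc()` sweeps all distinct scores and integrates
trapezoidally, which makes the AUC equal the Mann-Whitney concordance with
ties counted 1/2 — hence exactly 1.0 for a perfect separator and 0.5 in
expectation for random scores, the two analytic anchors the acceptance
checks pin down. Recall is sensitivity on the positive (transformed) class.

`promotion_call()` runs a one-way ANOVA over per-well counts by
concentration and Dunnett many-to-one comparisons against the control
(via multcomp, two-sided, the conventional toxicology default; an
independent multivariate-t computation serves as the oracle in the tests).
The chemical is called positive when two *adjacent* members of the tested
concentration ladder are both significant at alpha = 0.05. The ANOVA is
reported alongside; a `gatekeep` flag makes it a prerequisite for the
Dunnett calls, since practice varies on whether it should be one. If every
group's counts are exactly tied the statistics are undefined; the call
then falls back to strict mean elevation and is flagged degenerate.

A caution about plate size: with the usual 6 wells per concentration, a
TPA-like response (control counts near 0.2 +/- 0.4 foci per well, treated
concentrations near 2.2 +/- 1.5 to 2) gives Dunnett t-statistics around
2.2, short of the two-sided critical value (~2.53 for three comparisons at
20 residual df). Single-plate designs of this size often cannot support a
significant call at individual middle concentrations, and the example
plate shipped in `inst/extdata/tpa_plate_synthetic.csv` — built to have
exactly such moments — is accordingly called negative by the default
analysis even though its dose trend is visible by eye.

## Known limitations

* The synthetic generator plants class structure exactly along MD/ED/WPD;
  it cannot certify performance on real micrographs, staining variation,
  multi-focus fields, or out-of-focus images.
* The negative-class morphology is the package's construction; the assay
  literature describes negatives only loosely ("nontransformed cell
  clusters").
* The CNN engine is CPU-bound; the full 224x224, 50-epoch protocol is
  supported but slow on a single core. The scaled-down configuration above
  is the intended regime for testing.
* Dunnett p-values rely on randomized quadrature of the multivariate t
  distribution; they are reproducible only up to ~1e-4 and are therefore
  compared absolutely, not to machine precision.
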