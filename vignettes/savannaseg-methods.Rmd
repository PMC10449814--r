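---
title: "Methods: canopy segmentation, class weighting and landscape metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy segmentation, class weighting and landscape metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(savannaseg)
```

`savannaseg` is a complete desk-scale pipeline for per-pixel classification
of tree species in very-high-resolution RGB orthomosaics: synthetic scene
simulation, tiling and spatial splitting, augmentation, weighted CNN
training, offset-ensemble inference, accuracy assessment, and per-class
landscape metrics. This vignette explains the models and procedures, the
parameters that matter, the choices made where the design was genuinely
open, and what the package's tests do and do not demonstrate.

## The segmentation problem and its models

The input is an RGB raster (around 1.2 cm ground sampling distance for
consumer-UAV imagery flown at ~40 m, the package default) paired with a
single-band integer class mask. Classes are a dominant bare-ground/herb
background plus tree species; class shares are strongly imbalanced.

Three encoder-decoder architectures are provided through one graph-based CNN
engine with compiled kernels (im2col convolution with dilation, 2x2 max
pooling, nearest-neighbour upsampling, full backpropagation, Adam):

- **U-Net**: symmetric encoder/decoder, two 3x3 ReLU convolutions per stage,
  channel-doubling on descent, skip concatenations on ascent.
- **FC-DenseNet**: dense blocks (each layer convolves the running
  concatenation and is concatenated back in) on both the down and up paths,
  1x1 transition convolutions before pooling.
- **DeepLabv3+**: an encoder whose deepest features pass through atrous
  spatial pyramid pooling — one 3x3 dilated branch per configured rate plus
  a global-average-pooling branch — followed by a decoder that fuses a
  low-level feature map.

All three are built at configurable scale (`depth`, `base_width`,
`atrous_rates`, `growth_rate`, `block_layers`). The study-scale variants of
these networks train for days on GPUs; the package treats them as
configuration presets and validates the architectures' contracts (output
resolution, probability simplex per pixel, branch structure, parameter-count
monotonicity) plus end-to-end learning at small scale. Upsampling is
nearest-neighbour throughout, including the DeepLabv3+ decoder, a
simplification at these model sizes where bilinear interpolation offers no
measurable benefit.

## Class imbalance and the loss

With class shares `p_i` (proportion of training pixels), loss weights are

    w_i = 1 / p_i^x,   x >= 0

so `x = 0` disables weighting and larger `x` boosts rare classes; classes
absent from the training data are assigned weight 0 and thereby excluded
from the loss. Architecture-default exponents are 0.1 (U-Net), 0.005
(FC-DenseNet) and 0.2 (DeepLabv3+). The loss is the weighted categorical
cross-entropy, the mean over pixels of `w_c * (-log p_hat_c)` with the
predicted probability clipped below at 1e-7 before the logarithm — purely a
numerical safeguard, far below any metric tolerance.

## Training protocol

Adam with initial learning rate 1e-4, `beta1 = 0.9`, `beta2 = 0.999`;
at most 300 epochs, stopping once 40 consecutive epochs pass without a new
best validation mIoU; parameters snapshotted every epoch. Batch size
defaults to inverse scaling with tile area from 4 tiles at 1024 px
(`auto_batch_size()`); explicit values are accepted, since published
configurations do not always follow the inverse rule.

The tracked metric is mean intersection over union,

    mIoU = (1/n) * sum_i O_i / U_i

with `O_i` the class-i true positives and `U_i = TP + FP + FN`; classes with
an empty union are excluded from the mean. Validation scenes are predicted
with the base tile grid only (one zero-offset layer) rather than the full
16-layer ensemble — a deliberate divergence from test-time inference that
cuts validation cost by 16x and leaves epoch ranking essentially unchanged.

Because validation curves are noisy, the best epoch is not the raw argmax:
a degree-2 LOESS is fitted to validation mIoU versus epoch and the logged
epoch maximising the smoothed curve is selected, ties toward the earliest
epoch. The LOESS span is not part of the original protocol; 0.3 is the
package default, and spans too small for the fit raise an error suggesting a
larger one. Pipeline runs shorter than three epochs fall back to the raw
argmax.

## Augmentation

On-the-fly, label-consistent: random horizontal flip (p = 0.5), rotation
within ±0.35 rad, scaling in [0.9, 1.1], brightness ±25%, contrast 50–200%,
saturation 60–175%. Published protocols name these operations and ranges but
not their colour-space definitions or order; the package's reading, fixed
and documented:

- order flip → rotate → scale → brightness → contrast → saturation
  (geometric before photometric);
- brightness is a multiplicative factor in [1−δ, 1+δ] (the additive reading
  is the other defensible choice);
- contrast scales the deviation from the image mean;
- saturation scales the S channel in HSV space;
- rotation and scale are applied as one inverse-mapped resampling pass,
  bilinear for the image with reflection fill, nearest-neighbour for the
  mask with clamping to the nearest valid pixel — no ignore label is ever
  introduced, so the loss definition is unchanged.

An operation drawn at its identity value is skipped, so degenerate ranges
reproduce the input bit for bit (a tested invariant, and the reason
photometric floating-point round-off cannot masquerade as augmentation).

## Tiling, splits and offset-ensemble inference

Training tiles are non-overlapping squares on a grid from the top-left
origin; partial tiles at the right/bottom edges are discarded (count =
`floor(H/T) * floor(W/T)`), because padding would inject synthetic pixels
into the loss. Splits operate on whole scenes only: train, validation and
test never share a scene, the guard against spatial autocorrelation
inflating apparent accuracy.

Test-time inference writes 16 layers: tile grids offset by 0, 25, 50 and 75%
of the tile size in each axis (the 4 x 4 Cartesian product, zero offset
included). For each layer the scene is reflection-padded so a full grid
covers every pixel — the edge policy is not part of the published scheme;
reflection keeps edge statistics natural and gives every pixel exactly one
vote per layer. The final prediction is the per-pixel majority vote over
hard class ids, ties to the lowest id; vote-on-probabilities is deliberately
not the default, matching the literal majority-vote rule.

## Accuracy assessment

From the confusion matrix (rows = truth, columns = prediction; a transposed
orientation is common in figures): per-class precision, recall,
`F1 = 2PR/(P+R)` with 0/0 defined as 0 and flagged, unweighted mean F1,
overall accuracy, Cohen's kappa `(OA - p_e)/(1 - p_e)` with
`p_e = sum_i rowsum_i * colsum_i / total^2`, and mIoU (computed from the
matrix by an independent code path from the mask-based implementation; the
two are cross-checked in the tests). Whether mean F1 should include the
background class is ambiguous in practice, so both modes exist; the default
includes it, `exclude_class` drops it. Paired t-tests compare per-class F1
vectors between configurations (df = n − 1, two-sided); no multiple-testing
correction is applied, and constant difference vectors are rejected as
degenerate rather than scored.

## Landscape metrics

Patches are maximal connected components per class, 8-connectivity by
default (the common landscape-metrics convention), 4 available. Per class:
mean patch area (ha), total area (ha), and compactness
`1 - a_patch / a_circle` from the smallest circumscribing circle — 0 for
discs, approaching 1 for lines. The circle is computed on pixel *corner*
points (a single pixel is a unit square with radius sqrt(2)/2, not a point
of radius 0) by an incremental minimal-enclosing-circle construction on the
corner convex hull; tests verify it against a brute-force pair/triple
enumeration. Because "smallest circumscribing circle" can denote either the
circle's absolute size or the ratio-based compactness, both are exported
(`mean_circle_area_ha`, `mean_compactness`); regressions default to the
ratio. Per-class F1 is regressed on each metric by OLS with `df = n - 2`
(16 vegetation classes, background excluded, give df = 14); a constant
metric raises an error rather than a fit.

## The synthetic-scene generator

Real reference data for this problem are field-delineated orthomosaics that
no public archive provides, so the package generates labelled scenes with
the same statistical structure: a dominant background class, strongly
imbalanced patchy vegetation classes, and class-specific fine-grained
texture — the feature scale that actually separates savanna species, in the
absence of distinctive large-scale crown shapes.

Mask synthesis places randomly oriented elliptical patches (area ~
Gamma(shape 4) around the class's `patch_area_mean`, truncated at 4x;
eccentricity from `elongation`) by rejection sampling until each class's
pixel budget (`target_proportion` x scene area) is met; later classes never
overwrite earlier ones, and the background absorbs the rest — masks are
single-label by construction. The image paints each class as its base colour
plus band-passed Gaussian noise at the class's `texture_scale` (granule
size), plus fine white-noise grain. All randomness flows from one explicit
seed through a local RNG that never touches global state; `(spec, seed)`
determines the scene bit for bit. The generator keeps a ledger of pixels
actually claimed per class (`pixel_budget`), which the landscape metrics are
tested against.

The phenology-shift perturbation (`perturb_scene`) applies a
class-conditional colour shift plus texture drift, both scaled linearly by
`strength`, leaving the mask untouched; strength 0 is the identity. It is a
qualitative stand-in for the morphological change between recording
campaigns months apart — no quantitative description of that variance
exists, so the perturbation is not a calibration target, only a monotone
stressor.

What passing tests therefore show: the pipeline's computations are correct
and the training loop can learn separable classes end to end. What they do
not show: performance on real imagery, whose within-class morphological
variance, photogrammetric artefacts, data gaps and genuinely ambiguous class
boundaries the generator does not emulate.

## Problem sizes and numerical choices

The shipped end-to-end preset (`preset_separable_config()`) uses three
separable classes (70/18/12%), 192 px scenes (two training, one validation,
one test), 64 px tiles, a depth-2 U-Net with 8 base channels, and at most 25
epochs at learning rate 1e-3 with batch size 2. The learning rate departs
from the 1e-4 default deliberately: a model of ~7.5k parameters trained for
a few hundred Adam steps needs a larger step size, whereas 1e-4 is
appropriate for the multi-million-parameter, multi-day regime the default
describes. The preset reaches held-out mean F1 around 0.98 in about two
minutes on one CPU, and its perturbation ladder (0, 0.5, 1) decays
monotonically.

Other numerical conventions: He initialisation; softmax stabilised by
row-max subtraction; loss clip 1e-7; LOESS tie-break to the earliest epoch
within 1e-12; majority-vote tie-break to the lowest class id; compactness
clamped to [0, 1] against discretisation round-off; scenes and masks
persisted as 8-bit PNG with CSV sidecars (lossless for class ids up to 255),
which is also why class ids are capped at 255 on write.

## Known limitations

- No GPU path; study-scale training is out of reach by design.
- Georeferencing is not carried through I/O (plain rasters, not GeoTIFF).
- The perturbation model is linear in appearance space; real phenology also
  changes geometry (leaf-off crowns), which is not emulated.
- FC-DenseNet and DeepLabv3+ are validated structurally and by small-scale
  learning, not against reference implementations.
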