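---
title: "Deeply supervised U-Net segmentation of whole-slide tumor sections: models, balancing, and the sectionwise decision"
author: "wsiseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deeply supervised U-Net segmentation of whole-slide tumor sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Assessing resection margins of basal cell carcinoma (BCC) requires deciding,
for every physically separate tissue section on a glass slide, whether it
contains tumor. `wsiseg` implements that pipeline as a reusable toolkit: a
U-Net segments each 512-pixel RGB patch into per-pixel Tumor/Normal
probabilities; overlapping patch predictions are stitched into a per-section
heatmap; thresholded connected regions are filtered by physical area (square
micrometres); and a section is called *Tumor* iff any region survives the
filter. Everything runs on CPU at configurable scale, and a synthetic
histology-like fixture generator stands in for real slide data, which cannot
be redistributed.

## Model

Two encoders are provided. The *vanilla* encoder follows the classical U-Net
contracting path: an initial 7×7 convolution with stride 2 (64 filters at
reference width), then one block per scale with two 3×3 convolutions, the
first strided, doubling the channel count while halving resolution. The
*resnet34* encoder is the convolutional backbone of a 34-layer residual
network (stem, 3×3 max-pool, four stages of basic residual blocks),
exposing the same five feature scales at 1/2 … 1/32 of the input. Every
convolution except the 1×1 score heads is followed by batch normalization
and ReLU, and padding preserves spatial size.

The decoder has `k` blocks (default 5). Each block bilinearly upsamples by
2, concatenates the symmetric encoder feature (the last block has no skip
connection), and applies two 3×3 convolutions. Each block additionally
carries a 1×1 score head producing a 2-channel pre-activation map
`score_l`; after a per-pixel softmax this is the block's probability map
`psi_l`, of spatial size `inputSize / 2^(k-1-l)` — 32·2^l for the reference
512-px geometry. The final output is `psi_{k-1}` unless the linear merge is
active.

Decoder channel widths are not fully determined by the source description
("halving the number of feature channels"); we start from the bottleneck
count, halve per block, and floor at 16, which keeps small test networks
well-formed. `baseWidth` scales every width so a width-8, 64-px network has
the exact topology of the reference width-64, 512-px network; this is what
makes CPU-scale end-to-end tests meaningful.

### Training strategies

* **plain** — Focal-Loss on the final map only.
* **deep supervision** — the loss is the sum over blocks `l = 0..k-1` of
  the Focal-Loss between `psi_l` and a downsampled target, with equal
  per-scale weights (re-weighting the scales was reported not to help, so
  we do not expose weights).
* **linear merge** — a trainable weight vector `w` of length `k` combines
  the bilinearly upsampled pre-activation score maps; the softmax is
  applied once, after the combination. `w = (0, …, 0, 1)` reproduces the
  plain model exactly, which we assert in tests.

The Focal-Loss is the per-pixel `-(1 - p_t)^gamma log p_t` with
`gamma = 2.0`, averaged over pixels. Whether the reference reduction was
mean or sum per patch is not documented; we use the mean and document it
here (the choice only rescales the learning rate). Probabilities are
clamped to `[1e-7, 1]` inside logarithms.

The target-downsampling operator `downsampleTarget()` is likewise
underdetermined by its signature (`{0,1}^{512×512×2} -> {0,1}^{32·2^l ×
32·2^l × 2}`). We use class-preserving max-decimation: a coarse cell is
Tumor if *any* constituent pixel is Tumor, then the map is re-one-hot.
This preserves thin tumor strands at coarse scales, where mean-pooling
followed by rounding would erase them. The operator is isolated behind one
function so the dialect can be swapped.

Optimization is Adam (β₁ = 0.9, β₂ = 0.999 — conventional values, not
documented in the source) with learning rate 5e-4 multiplied by 0.8 every
5 epochs, batch size 64, at most 40 epochs at reference scale. After every
epoch the mean validation IoU of the thresholded final map is recorded and
the five best epochs are retained as checkpoints. The whole engine
(convolution via im2col/GEMM, batch-norm, bilinear resizing with the
half-pixel convention, the reverse-mode tape) is implemented in
R/RcppArmadillo and verified against finite-difference gradients in the
test suite; bilinear upsampling uses the `align_corners = FALSE`
convention throughout, fixed and documented here.

## Patch balancing

Tumor-free tissue dominates training slides, so patches are resampled by
annotation coverage. For each tile the fractions of pixels covered by
*Tumornest* (T), *Stroma* (S) and *Normal* (N, distractors) polygons are
computed by scanline rasterization at pixel centers. Patches fall into five
*disjoint* categories with precedence `T>=10%` > `T>=0.05%` > `S>=0.05%` >
`N>=0.05%` > background (`T<0.05%`); the precedence resolves the otherwise
ambiguous overlap between stroma/distractor patches that also contain
tumor, and ties at a threshold go to the higher category. Treating the
categories as a partition is supported by the reference per-category counts
summing exactly to the reference totals (209,390 before resampling and
255,771 after). `buildResamplingPlan()` assigns per-patch repetition counts
round-robin within each category, so counts sum exactly to the category
target and differ by at most one; no patch is ever dropped. The pixel
unbalance statistic — tumor-free over tumor pixels — quantifies the effect.

Augmentation applies one shared geometric warp (flips, 90° and small
continuous rotations, ±10% zoom, elastic deformation from a smooth random
displacement field) to image and mask — the mask is resampled with
nearest-neighbour so it stays one-hot — plus image-only smoothing and color
jitter. Magnitudes are not prescribed; defaults are conservative and fully
exposed in `augmentConfig()`.

## Inference and the sectionwise decision

Tissue sections are detected on the bright scanner background by intensity
and saturation thresholding and 8-connected grouping. Each section is
covered with `inputSize`-px tiles overlapping by at least 50% per axis
(`planTiles()`: evenly spaced integer origins, derived count formula).
Overlapping tile predictions are combined by the per-pixel arithmetic
mean — the combination rule is not documented in the source; the mean is
order-invariant and smooths tile-border artifacts, which we prefer over
max (more false positives) or last-wins (order-dependent). The heatmap is
thresholded at `probability >= predictionThreshold`, connected components
are extracted (8-connectivity by default, so thin diagonal strands stay
whole; switchable), their areas converted to µm² via `mpp²`, and regions
below `areaThresholdUm2` are discarded. The section is *Tumor* iff a region
survives. Both thresholds compare with `>=`. Working-magnification `mpp`
defaults to 0.92 µm/px where metadata is absent, but every fixture and
reader carries explicit `mpp`.

Both thresholds are selected by an exhaustive grid search maximizing the
F-beta score (β = 1.5, so recall — a missed tumor section — outweighs
precision) on sectionwise validation labels, with heatmaps computed once.
Grid-search ties are broken by higher sensitivity, then lower prediction
threshold, then lower area threshold: a deliberate, documented rule since
the source states none. Default grids are prediction 0.30–0.80 in steps of
0.05 and area thresholds at multiples of 1280 µm² up to 10,240, covering
all the reference operating points of the four model variants.

Deep supervision makes every decoder block's head a usable output:
`truncatedForward()` runs the encoder plus a decoder prefix and upsamples
that block's probability map, trading boundary detail for speed.
`perBlockEvaluation()` repeats the sectionwise evaluation for every block
with the same thresholds, sharing one full forward pass per tile (the
per-block maps are read off the same tape), so the per-block table is
cheap and the last row is *identical* to the full-model evaluation by
construction.

## Synthetic fixtures

`generateSection()` renders a tissue blob on a bright background, tumor
nests as dark purple textured blobs with stroma halos, and follicle-like
distractors (dark rim, bright core) annotated as *Normal*. Polygons are
exact: nest outlines are irregular star-convex blobs rescaled so the
shoelace area matches the requested area, and rasterization at pixel
centers reproduces it to within discretization error. A section's label is
*Tumor* iff it has at least one nest, by construction.

The default conditions (`fixtureParams()`) are chosen once as a CPU-scale
study: sections of 256–384 px at 2 µm/px; 16 train / 8 val-I / 24 val-II /
64 test sections mirroring the detailed-vs-sectionwise annotation split of
the reference data; prevalence 0.5; 1–3 nests of mean 30,000 µm² (min
15,000); 30 µm stroma halos; 0–3 distractors of 500–3,000 µm². Distractor
areas sit an order of magnitude below nest areas so the area filter — not
the segmentation alone — resolves them, exactly the failure mode the
filter exists for. The training network for the end-to-end study is a
vanilla-encoder U-Net with 64-px patches, `k = 4`, base width 8, batch
size 8, 14 epochs: small enough to train in minutes on one CPU, large
enough to reach validation IoU well above the 0.7 learnability bar and to
fit the coarse `psi_0` head, whose discrimination of distractors matures
later in training than the full decoder's.

What the fixtures deliberately do not emulate: realistic H&E appearance,
scanner artifacts, stain batch effects, multi-resolution pyramids, or
ambiguous tumor subtypes. Passing the end-to-end tests therefore shows the
*pipeline* is correct and learnable-by-texture, not that the model would
reach the reference accuracy on real slides — the real data is not
deposited and reference-scale training is out of reach of a CPU test
suite.

## Numerical choices and degenerate inputs

* Probabilities clamped to `[1e-7, 1]` in logarithms; gradients clamp both
  ends.
* Batch-norm uses ε = 1e-5 and momentum 0.1 for running statistics;
  evaluation mode freezes them, and train/eval is an explicit argument,
  never ambient state.
* IoU of two empty masks is defined as 1 (an empty prediction of an empty
  truth is correct).
* Metrics with empty denominators (no predicted positives, say) return
  `NA` with a warning rather than `NaN`; a zero-section evaluation and an
  all-zero-tumor unbalance are errors.
* An F-beta with precision = recall = 0 is signalled as undefined; the
  grid search skips such grid points.
* Sections smaller than a patch get one padded (white) tile; padding never
  enters the stitched heatmap.
* Self-intersecting annotation polygons are rejected with a diagnostic
  naming the offending edges.
* Coordinates are 0-based and half-open everywhere (tiles, boxes, polygon
  pixel frames).

## Known limitations

* The reverse-mode engine supports exactly the layer set these
  architectures need; it is not a general autodiff.
* GeoJSON rings with holes are not supported (fixtures never produce
  them).
* The resnet34 topology is fixed to `k = 5`; the vanilla encoder
  generalizes to any `k >= 1` with `inputSize` divisible by `2^(k+1)`.
* ImageNet initialization of the residual encoder is not provided (no
  pretrained weights are shipped); initialization is always random,
  seeded.
* Training is single-threaded and CPU-bound by design; there is no mixed
  precision or multi-GPU path.
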