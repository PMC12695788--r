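---
title: "Multi-domain enhanced detection for small fruit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-domain enhanced detection for small fruit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Counting small fruit (here: bayberries) in orchard photographs is a
small-object detection problem under hard conditions: targets of a few dozen
pixels, dense clusters, heavy leaf occlusion, and strong illumination
variation. `berrydetr` re-implements a real-time detection-transformer
(DETR-family) architecture specialized for this setting, together with the
dataset pipeline and evaluation stack around it. Query-based detection
removes the need for non-maximum suppression: a fixed set of object queries
is decoded end-to-end into scored boxes.

The detector has the usual three stages:

* **backbone** — feature extraction at strides 4/8/16/32 (`P2`..`P5`);
* **neck** — multi-scale fusion of the pyramid;
* **head** — a transformer decoder over the fused maps with IoU-aware
  query selection.

The package provides a faithful baseline (ResNet-18 backbone, single-layer
intra-scale attention encoder on `P5`, a cross-stage fusion neck of
reparameterized convolution blocks, and a 3-layer/300-query/256-wide
deformable decoder) and three replacements that define the enhanced model:

1. **EFENet**, a backbone of multi-path feature-enhancement (MFEM) blocks
   built on reparameterized convolutions;
2. **MDFFN**, a multi-domain fusion neck combining lossless space-to-depth
   downsampling, omnidirectional large-kernel convolution, and
   frequency-domain attention, extended down to `P2`;
3. **ADSample**, learnable deformable downsampling.

## Reparameterized convolution

During training a RepConv runs three parallel branches — a 3x3 convolution,
a 1x1 convolution, and (when shapes permit) an identity path realized purely
as batch normalization — each with its own normalization; the sum passes
through SiLU:

$$F = \sigma\!\big(\mathrm{BN}_3(W_{3\times3}*X + b_3) +
\mathrm{BN}_1(W_{1\times1}*X + b_1) + \mathrm{BN}_{id}(X)\big).$$

At inference the three branches fold exactly into one 3x3 convolution:
normalization statistics fold into kernel and bias
($W' = W\gamma/\sqrt{v+\varepsilon}$,
$b' = \beta + (b-\mu)\gamma/\sqrt{v+\varepsilon}$), the 1x1 kernel zero-pads
onto the centre tap, and the identity path becomes a diagonal-unit kernel.
Because the activation is applied after the branch sum, fusion is exact to
numerical precision; `rep_fuse()` performs it and `fuse_model()` /
`convert_checkpoint()` convert whole models and saved weights. Each branch
carries its own normalization — the fold of three separate statistics into
one kernel requires it.

## EFENet and the MFEM block

An MFEM block expands its input with a 1x1 convolution to `2*hidden`
channels and splits the result into an untouched branch `F1` and a
processing branch `F2`. `F2` passes through a RepConv, then `n - 1` cascaded
3x3 convolutions, then a closing 1x1 adjustment; the concatenation
`[F1, Frep, Fm_1, ..., Fm_{n-1}, Fcv4]` (`(n+2) * hidden` channels) is fused
by a final 1x1 convolution. The backbone is a two-convolution stem (stride
2) followed by four stages, each a stride-2 downsample plus a stack of MFEM
blocks, emitting `P2/4` through `P5/32`.

Defaults: stage widths 64/128/256/512 with a 32-channel stem (the familiar
ResNet-18-like pyramid; the baseline neck then slots on unchanged), branch
width one half of the stage width, stage depths `(1, 2, 1, 2)` and cascade
settings `n = (2, 2, 2, 1)`. Depths and `n` were fixed once against the
package's analytic parameter counter so that the backbone, mounted under the
standard encoder/decoder, reproduces the published model scale (13.8 M
parameters for the backbone-swapped variant); they are ordinary config
entries and can be changed freely.

## The multi-domain fusion neck

Both necks share one pyramid skeleton: lateral 1x1 units on the upper level,
2x nearest upsampling, concatenation with the level below and a fusion block
per node on the way down; then downsampling, concatenation and a fusion
block per node on the way up. The baseline uses cross-stage blocks of
RepConvs and strided-convolution downsampling; the multi-domain neck swaps
in the following components.

**SPDConv** rearranges each 2x2 neighbourhood into four channel groups
(sub-maps ordered (0,0), (1,0), (0,1), (1,1) over row/column offsets) —
a bijection on pixels, so downsampling discards nothing — and follows with a
3x3 convolution on the 4x channels. In the neck a 1x1 reduction precedes
the rearrangement (defaults 64/96/192 at the three bottom-up nodes) to keep
the 4x expansion affordable.

**CMKBlock / MDCM.** A 1x1 convolution opens the block; 25% of the channels
pass through the multi-directional convolution module, the remaining 75%
pass through untouched, and a 1x1 convolution fuses the concatenation. MDCM
preprocesses with a GELU-activated 1x1 convolution and adds four depthwise
responses — 1x1 point, 1x31 and 31x1 strips (padded (0,15)/(15,0)), and a
31x31 square kernel (padded 15), so all terms align spatially — plus an
attention branch, under a residual ReLU.

**DDAM.** Frequency-channel attention first: per-channel weights from
global average pooling through a linear map gate the channel spectra,

$$F_{fca} = \left|\mathcal{F}^{-1}\!\big(W_{f}\,\mathrm{GAP}(F_{in}) \odot
\mathcal{F}(F_{in})\big)\right|,$$

then spatial-channel attention rescales channels by weights pooled from
$F_{fca}$. The attention weights are the raw linear outputs (no squashing
nonlinearity); the spatial gate's matrix is zero-initialized so the
multiplicative branch grows from a neutral state during training.

**FMB.** Two parallel 1x1 convolutions produce $F_1$ and $F_2$; the
spectrum of $F_2$ is gated elementwise by $F_1$ in the complex domain, and

$$F_{FMB} = \alpha \odot \left|\mathcal{F}^{-1}(F_1 \odot
\mathcal{F}(F_2))\right| + \beta \odot X$$

with learnable per-channel $\alpha$ (init 0) and $\beta$ (init 1), i.e. the
block starts as the identity. Inside MDCM the attention branch is
`FMB(DDAM(F_in))`.

**FFT convention.** Unnormalized forward transform, $1/(HW)$ inverse (the
base-R `fft()` convention). The choice is observable — the magnitudes above
scale with it — so it is pinned here and the test suite checks the blocks
against dense DFT-matrix oracles under the same convention.

**P2 in the pyramid.** The multi-domain neck extends the top-down path to
`P2` and folds the result back into `P3` bottom-up; the decoder keeps
consuming three scales (8/16/32), so decoder cost is unchanged. The P2 entry
node (lateral units, its fusion block and its space-to-depth descent) runs
at width 160 rather than the 256 used at `P3`-`P5`: at full width the
160x160 maps alone would add roughly 3 GMACs beyond the published compute
budget, and the narrower entry is what reconciles the printed parameter
count (14.7 M) with the printed 55.5 GFLOPs. This is the one place the
package deviates from "one width everywhere"; it is a plain config entry
(`p2_width`).

## Adaptive deformable sampling

A 3x3 convolution at the downsampling stride predicts `2N` offsets per
output location (zero-initialized, so training starts from regular
sampling). Sampling coordinates are `P = P0 + Pn + Delta`: the stride-spaced
base grid, plus a fixed `n x n` pattern template covering the stride window
(`N = n^2`; default `N = 4` for stride 2 — the smallest template that tiles
the window), plus the learned offsets. Features are gathered by bilinear
interpolation with zero weight outside the grid — the stencil weights
`max(0, 1-|dx|) max(0, 1-|dy|)` form a partition of unity inside the image
and make the sampler differentiable in both the features and the
coordinates. The `N` samples per output cell stack along the height axis and
an `(N, 1)` column convolution with stride `(N, 1)` aggregates them,
followed by SiLU. With zero offsets the module is exactly a patterned
strided convolution (a property the tests assert); coordinates are 0-based
pixels, `x` = column, with no normalization to `[-1, 1]`.

Placement: ADSample replaces the stride-2 convolutions at the backbone's
stage-2 and stage-3 transitions (the placement list is a config entry). The
necks keep their own downsamplers — space-to-depth is the multi-domain
neck's defining downsampler, and swapping the baseline neck's strided
convolutions as well would move the "downsampling only" ablation far
outside its published half-megaparameter envelope.

## Detector assembly

The decoder follows the standard real-time DETR layout. An encoder head
scores every fused-map token; the top-`k` (`k` = 300 queries) tokens
initialize the object queries, their box heads refining grid anchors
(anchor size 0.05 at stride 8, doubling per level) in logit space. Each of
the 3 decoder layers applies self-attention, multi-scale deformable
cross-attention (8 heads, 4 sampling points, 3 levels, bilinear sampling
with the same stencil as ADSample), and a feed-forward block, refining boxes
layer by layer. Score heads are initialized to a 0.01 positive prior and
box heads to zero (boxes start exactly on their references) — both standard
for this family and, in the package's experience, the difference between a
short overfitting run converging or not.

Because query selection is a hard top-`k`, the training objective is only
piecewise smooth: an optimizer step taken exactly at a selection boundary
can raise the loss even for tiny learning rates. This is a property of the
architecture family, not of this implementation; the trainability tests use
generic configurations.

**Complexity accounting.** `count_parameters()` counts trainable scalars
(normalization running statistics are buffers). `count_flops()` runs one
forward pass under an operation meter and reports
2 FLOPs per multiply-accumulate over convolutions, dense layers and
attention matmuls — elementwise work, resampling and FFTs are excluded.
The convention was pinned once so that the reproduced baseline lands at the
published baseline figure (57.5 G here vs 56.9 G printed) and then frozen;
under it the full model reports 55.3 G against 55.5 G printed.

**Loss.** Hungarian matching (an exact rectangular assignment solver,
tested against exhaustive enumeration) under the usual class + L1 +
generalized-IoU cost (weights 1/5/2), BCE classification over all queries,
box losses on matched queries, with auxiliary losses on every decoder layer
and on the selected encoder outputs. Nothing in the loss deviates from the
baseline recipe.

**Normalization semantics.** Batch normalization runs in inference mode
(stored statistics) by default; `bd_train_mode()` switches to per-map
statistics with running-stat updates, and `bd_refresh_stats()` re-estimates
statistics after a fit ("precise BN"). RepConv fusion always uses the
stored statistics — fusion is an inference-time identity. For the short
overfitting demonstrations the package fits with frozen statistics
(`train_bn = FALSE`): with single-image batches the statistics noise
otherwise dominates at this scale.

## Dataset pipeline

`split_dataset()` shuffles deterministically under a seed and takes
`floor(0.7 n)` / `round(0.2 n)` / remainder — the rounding that reproduces
the published 1367/391/196 partition of 1954 images. `augment_offline()`
expands a set to `factor` times its size (originals included, matching the
published 1367 -> 5468 at factor 4), drawing per copy one or two operations
from: rotation (±15°), horizontal/vertical flip, translation (±10%),
Gaussian blur/noise, brightness scaling, random crop, local occlusion.
Boxes transform as the axis-aligned hulls of their transformed corners,
clip to the frame, and drop below 20% remaining area (configurable).
YOLO text and COCO JSON annotation I/O round-trip losslessly at six-decimal
precision.

## The synthetic scene generator

`generate_scene()` renders what the detector is for: many small,
near-circular, shaded berries (red or green) in Poisson-distributed
clusters on a green value-noise background with darker leaf shapes, a
configurable fraction of berries partially hidden under leaf occluders, and
a global illumination gain. Ownership masks track per-berry visibility;
berries above the visibility threshold (default 25%) become ground-truth
boxes, whose centres match the rendered discs to sub-pixel accuracy.
Defaults (640 px, ~40 berries of radius 6-14 px, 30% occluded, gain
0.7-1.3) mirror the dense, occluded, small-target conditions of the study
imagery.

What the generator does **not** emulate: real leaf/branch texture
statistics, bokeh and motion blur, specular weather effects, fruit shape
variation beyond circles, or annotation noise. Tests passing on synthetic
scenes therefore demonstrate that the architecture, losses, pipeline and
metrics are implemented correctly and that the model can fit such imagery —
not that field accuracy on real orchards is reproduced; the published
accuracy figures require the original photographs.

## Problem sizes in the test suite

Mathematical property suites run at small tensor sizes (4x4 to 8x8 maps,
1-3 channels) where dense-DFT and sliding-window oracles are exact and
instant. Model-scale checks (parameter counts, FLOPs) build the full
640-pixel architecture — counting is analytic and one metered forward pass
suffices. The end-to-end trainability demonstration (`smoke_overfit()`)
uses 20 scenes at 96 px with 2-10 berries each and a reduced model
(2-layer decoder, width 48, 20 queries, ~0.5 M parameters), fitting with
Adam (peak 1.5e-3, 15-step warmup, decay at step 150, batch 5, global
gradient clipping) and stopping once training mAP50 reaches 90% — typically
by step 75-125. These sizes are the package's chosen desk-scale study
conditions; the generator's defaults, not the test budgets, define the
scene statistics.

## Known limitations

* Training here is a correctness demonstration, not a training system:
  no denoising queries, no EMA, no mixed precision, no multi-GPU.
* Small-batch normalization statistics are noisy; the package exposes
  frozen-statistics fitting and precise-BN refresh rather than synchronized
  batch statistics.
* The FLOP meter counts what the pinned convention defines; competitor
  counters that include elementwise or FFT work will read higher.
* The frequency-domain blocks are quadratic in their inputs; with
  normalization disabled or statistics frozen far from the activation
  distribution they can overflow under aggressive learning rates. Zero
  initialization of the gate scales and gradient clipping are the mitigations
  used here.
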