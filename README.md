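# berrydetr

Detection and counting of small fruit (bayberries) in cluttered orchard
imagery, as an R package. `berrydetr` re-implements a multi-domain enhanced
real-time detection transformer (MDE-DETR): a query-based, NMS-free detector
whose three replacements over the RT-DETR-style baseline target exactly the
failure modes of small-fruit imagery — tiny targets, dense clusters, and
occlusion. It is aimed at researchers in agricultural image analysis who
want an inspectable, fully tested reference implementation of the
architecture, its dataset pipeline, and its evaluation stack, with no
deep-learning framework dependency.

## What is inside

* **RepConv** — structural reparameterization: training with parallel
  3×3 + 1×1 + identity(BatchNorm) branches,
  `F = σ(BN₃(W₃ₓ₃∗X) + BN₁(W₁ₓ₁∗X) + BN_id(X))`, fused exactly into a single
  3×3 convolution for inference (`rep_fuse()`, `convert_checkpoint()`).
* **EFENet** — a backbone of multi-path feature-enhancement blocks
  (`Y = W_cv2 ∗ Concat[F₁, F_rep, F_m1, …, F_m(n−1), F_cv4]`) emitting a
  P2/4 … P5/32 pyramid.
* **MDFFN** — a fusion neck combining lossless space-to-depth downsampling
  (`F = W₃ₓ₃ ∗ Concat[X[::2,::2], X[1::2,::2], X[::2,1::2], X[1::2,1::2]]`),
  cross-stage multi-kernel blocks with omnidirectional depthwise kernels
  (1×1, 1×31, 31×1, 31×31), dual-domain attention
  `F_fca = |ℱ⁻¹(W_f GAP(F) ⊙ ℱ(F))|`, and a frequency-modulation block
  `α ⊙ |ℱ⁻¹(W₁X ⊙ ℱ(W₂X))| + β ⊙ X`, extended down to P2.
* **ADSample** — learnable deformable downsampling: predicted offsets
  `Δ = W_off ∗ X`, sampling coordinates `P = P₀ + Pₙ + Δ`, bilinear
  gathering, and an (N,1) column convolution.
* **Detector assembly** — baseline and enhanced variants with independent
  ablation flags, analytic parameter counting and a metered FLOP counter,
  Hungarian-matched DETR training loss with a tape-based autodiff engine,
  and NMS-free inference.
* **Data pipeline** — deterministic 7:2:1 splits, offline augmentation,
  YOLO/COCO annotation I/O, and a synthetic orchard-scene generator
  (clustered shaded berries, leaf occluders, illumination variation) so the
  whole stack runs with no downloads.
* **Evaluation** — greedy score-ordered matching, precision/recall,
  COCO-style 101-point mAP50 / mAP50:95, and the detection-to-counting
  linear regression (R², MAE, RMSE).

## Worked example

```r
library(berrydetr)
set.seed(1)

base <- assemble("rtdetr_r18")   # reproduced baseline
full <- assemble("mde_detr")     # all three replacements active
count_parameters(base)           # 19797172  -> 19.8 M
count_parameters(full)           # 14707148  -> 14.7 M
count_flops(full)                # 55.3 GFLOPs at 640x640
count_flops(base)                # 57.5
```

The parameter counts say the enhanced model is 25.7% lighter than the
baseline it replaces while its forward pass costs slightly less under the
same counting convention (2 FLOPs per multiply-accumulate over
convolutions, dense layers, and attention matmuls).

```r
sp <- scene_params(size = 320L, lambda = 25, radius_range = c(4, 9))
scenes <- generate_dataset(10, sp, seed = 7)
sapply(scenes, function(s) nrow(s$boxes))
#> 28 19 26 36 27 20 26 27 25 19        # labelled berries per scene
lengths(split_dataset(scenes, seed = 1))
#> train: 7  val: 2  test: 1            # the 7:2:1 partition
length(augment_offline(split_dataset(scenes, seed = 1)$train, factor = 4, seed = 2))
#> 28                                   # 7 originals + 21 augmented copies
```

Counting quality is summarized by an ordinary least-squares fit of machine
counts on reference counts:

```r
set.seed(3)
manual <- round(runif(50, 20, 140))
machine <- pmax(0, round(manual + rnorm(50, -2, 6)))
r <- count_regression(data.frame(machine = machine, manual = manual))
sprintf("slope %.3f intercept %.2f R2 %.4f MAE %.2f RMSE %.2f",
        r$slope, r$intercept, r$r2, r$mae, r$rmse)
#> "slope 1.001 intercept -1.47 R2 0.9709 MAE 4.46 RMSE 5.55"
```

End-to-end trainability at desk scale (reduced model, 20 synthetic scenes,
Hungarian-matched set loss):

```r
res <- smoke_overfit(seed = 1)   # ~5 minutes on one CPU
res$map50; res$steps_used
#> 93.6
#> 100                              # training mAP50 past 90% within 100 steps
```

A thin command-line wrapper over the same functions ships in
`inst/cli/berrydetr.R`
(`Rscript inst/cli/berrydetr.R build --variant full --summary`,
plus `synth`, `split`, `augment`, `infer`, `eval`, `count`).
Model weights serialize with `save_weights()` / `load_weights()` as a flat
named list keyed by dotted module paths (e.g. `backbone.s3b1.rep.w3`;
normalization statistics carry a `buf:` prefix); `convert_checkpoint()`
rewrites a multi-branch checkpoint into its fused single-branch form.

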