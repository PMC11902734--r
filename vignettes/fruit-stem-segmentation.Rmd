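---
title: "Ghost-bottleneck and global-attention instance segmentation for fruit and stem imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ghost-bottleneck and global-attention instance segmentation for fruit and stem imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Automated fruit handling (harvesting, stem removal in post-harvest
processing) needs a vision component that separates each fruit *and its
stem* as individual pixel-accurate instances in RGB images. The stem is the
hard part: it occupies a far smaller area than the fruit, is thin, often
partially occluded, and easily confused with background clutter.
`orchardseg` implements a complete single-stage instance-segmentation
stack for this two-class problem (class 0 = apple/fruit, class 1 = stem):
data model and label I/O, a synthetic scene generator with exact ground
truth, the network itself, training, inference, and COCO-style evaluation.
All numerical primitives - convolutions, batch normalization,
backpropagation, the optimizer - are implemented in the package (R with
C++ kernels; im2col + BLAS GEMM convolutions in single precision), so the
whole pipeline is self-contained and testable.

## The model

The detector follows the familiar single-stage anchor-free layout: a
backbone extracting features at strides 8/16/32, a pyramid neck fusing the
three scales, and a decoupled head that predicts, at every grid cell of
every scale, (a) a discrete distribution over `reg_max = 16` bins for each
of the four box-side distances, (b) per-class logits, and (c) 32 mask
coefficients combined with a shared bank of 32 prototype maps at stride 8.
Two modifications define the architecture:

* **Ghost bottlenecks** replace the three stride-2 downsampling stages of
  the backbone. A ghost module spends a 1x1 "primary" convolution on only
  `c2/r` of its output channels (`r = 2` by default) and generates the
  remaining channels with cheap 3x3 depthwise convolutions of the primary
  output, concatenating both. A ghost bottleneck stacks two ghost modules
  around an optional stride-2 depthwise downsampling and a
  squeeze-and-excitation (SE) channel gate, with an identity or
  depthwise + 1x1 shortcut. Weight count drops strictly below the dense
  convolution it replaces (for 16 -> 32 channels at 3x3: 400 versus 4608
  weights); `model_n_params(model, "backbone")` makes the comparison at
  full scale.

* **Global attention modules (GAM)** sit after the two neck stages that
  feed the stride-8 and stride-16 heads. The channel branch pools the map
  globally, passes the pooled vector through a two-layer network (SiLU
  inside, sigmoid outside) and rescales channels; the spatial branch then
  applies two 7x7 convolutions (channel reduction then restoration,
  sigmoid outside) and rescales positions. Both gates lie in (0, 1), so
  with all parameters zero the module scales its input by exactly
  0.25 - a property the test suite asserts.

The SE gate uses a ReLU inner activation; the GAM channel branch uses
SiLU. Both follow their respective defining equations; the difference is
deliberate and covered by tests.

### Design choices where the architecture is open

Several details are not pinned down by the published description of this
family of models; the package fixes them as follows and treats them as its
own conventions:

* Every convolution carries batch normalization and SiLU, except the final
  projections of the SE/GAM branches (sigmoid, no normalization) and the
  shortcut's 1x1 projection (normalization only).
* Ghost ratio `r = 2`, primary convolution 1x1, cheap operation 3x3
  depthwise.
* SE is enabled in the stride-2 bottlenecks (all three downsampling stages
  here); `model_spec(se_mode = ...)` switches it to all or none.
* GAM and SE reduction ratios default to 4; the GAM spatial kernel
  defaults to 7 and is configurable.
* The spatial-attention input is the channel-attended map, and its output
  gate has full channel resolution (elementwise product).
* One stated layer table row lists no stride for the final neck
  convolution; alignment with the stride-32 pyramid level forces stride 2,
  which the graph adopts.
* The head follows the standard decoupled design (separate box / class /
  coefficient branches with distribution-bin box regression and a
  prototype mask head at stride 8). To keep single-CPU training
  affordable, each branch uses one 3x3 stem at a quarter of the scale's
  channels rather than the reference's two full-width stems; this is a
  capacity choice, not a structural one.
* Batch-norm statistics: batch statistics during training, running
  averages at inference, eps 1e-3, momentum 0.03. The running-average
  update uses a cumulative average for the first updates (momentum
  `max(0.03, 1/t)`), so eval-mode inference is well-conditioned from the
  first epoch instead of amplifying barely-initialized statistics through
  thirty-odd normalized layers.

### Width/depth scaling and the tiny preset

`model_spec()` realizes the nominal scale: backbone channels 64-1024 and
C2f iteration counts 3/6/6/3 (neck 3/3/3/1). `preset = "tiny"` scales
widths by 0.25 and depths by 0.34 at 320 px input. The tiny preset exists
to make desk-scale CPU training feasible; it is an extension for testing,
not a published operating point.

## Training

Target assignment is task-aligned: each ground truth claims its top-10
in-box anchors by the score `p_cls^0.5 * IoU^6`, conflicts resolve to the
highest score. The loss has four components - complete-IoU box loss,
binary cross-entropy classification over all anchors, distribution focal
loss over the two bins bracketing each true side distance, and per-pixel
binary cross-entropy between the assembled prototype mask and the ground
truth, cropped to the target box and normalized by its area - combined
with weights 7.5 / 0.5 / 1.5 / 1.0.

The optimizer is SGD with momentum 0.937, weight decay 5e-4 and initial
learning rate 0.01 (up to 500 epochs with early-stopping patience 100 at
full scale), three warmup epochs and a cosine decay to 1% of the initial
rate. Weight decay applies to convolution and gate weights, not to biases
or normalization parameters. Gradients flow through every block via
hand-derived backward passes; the CIoU gradient with respect to the four
decoded side distances is evaluated by central differences (the
surrounding chain rules are analytic), which is numerically robust and
negligible in cost because it touches only positive anchors.

Augmentations are label-consistent by construction: quadrant mosaic (four
samples rescaled into one canvas split at a random interior point),
horizontal/vertical flips, whole-pixel translations with polygon clipping
(Sutherland-Hodgman against the unit square), and optional coarse cutout
as the interpretation of "dropout" augmentation (patches of gray; labels
untouched; off by default). Augmentation settings are held constant over
the whole run, so the per-epoch training-loss curve is measured on a
stationary distribution and losses from different epochs are directly
comparable.

## The synthetic scene generator

`generate_scene()` emulates the statistical structure of fruit-and-stem
imagery rather than its appearance: 1-3 shaded elliptical fruits
(radius 0.12-0.30 of the canvas; red/green/yellow palette with a radial
highlight and additive noise), each carrying exactly one thick
quadratic-curve stem (length 0.05-0.15 of the canvas, width 2-6 px)
attached at its top boundary, over plain / gradient / textured / dark
backgrounds (mirroring open-table, chamber and turntable acquisition
variety; the default "mixed" samples one per scene) with a global
illumination gain of 0.6-1.4. Instances are painted *from the very
polygons that are emitted as ground truth*, so annotation masks and
painted regions coincide exactly, up to stems overdrawing a sliver of
their own fruit when the stem root dips inside it (probability 0.15),
which mimics stem-fruit occlusion.

Two constructive rules keep scenes well-posed. Stem width is capped so a
stem's area stays below a fifth of its fruit's area (binding only on tiny
canvases). Placement uses whole-scene rejection sampling: a scene attempt
places fruits greedily with later fruits drawing radii from a range
truncated by `1/sqrt(i)` so several can share the canvas; if any fruit
fails, the entire layout is redrawn (up to 100 attempts, then an error).
Per-scene seeds are `seed + i`, so any single scene regenerates in
isolation.

What the generator does *not* model: real textures, leaves and branches,
specular highlights, camera noise statistics, perspective, depth. Passing
tests on synthetic scenes therefore demonstrate that the implementation
learns and evaluates correctly, not that the trained weights transfer to
orchard photographs.

## Inference and evaluation

`segment_image()` resizes anisotropically to the model's square input
(the letterboxing alternative exists as an opt-in in
`resize_to_square()`), decodes box distributions by softmax expectation,
thresholds class scores at 0.25, applies class-wise greedy NMS at IoU 0.7,
assembles each survivor's mask as the sigmoid of its linear combination of
prototypes, bilinearly upsamples to the original raster, thresholds at 0.5
(>= 0.5 is foreground, so an all-zero coefficient vector yields a full-box
mask), and zeroes the mask outside the detection box.

Evaluation is COCO-style: greedy score-ordered matching at a given IoU
threshold, 101-point interpolated average precision, mAP@50-95 as the
mean over thresholds 0.50-0.95 in steps of 0.05, box and mask modes
independent, per-class rows plus an unweighted "all" mean (scalar
precision/recall are reported at the per-class confidence maximizing F1,
since a fixed operating point is not part of the metric's definition).
Mask IoU is computed at the original image resolution.

## Numerical choices and limitations

* Network arithmetic is single precision; block-level forward paths agree
  with double-precision loop oracles to ~1e-6 relative at unit scale, and
  the tests pin them at 1e-5.
* Polygon rasterization is even-odd with pixel-center sampling; an
  exhaustive point-in-polygon oracle covers random polygons in tests.
* Bilinear resizing uses half-pixel sample centers with edge clamping
  everywhere (images, masks, prototypes, mosaic tiles).
* Logistic activations clamp their exponent at +/-80 so overflow cannot
  propagate NaNs from extreme pre-activations.
* NMS ties break toward the lower candidate index; matching ties toward
  the higher IoU.
* Boxes are half-open `[x_min, x_max)` in 0-based pixel coordinates with
  pixel centers at `x + 0.5`; normalized storage follows the
  YOLO-segmentation dialect.
* The training loop is deterministic given a seed (single-threaded BLAS);
  identical configuration and seed reproduce identical loss curves.

### Problem sizes used by the checks

Training the full nominal model on real data is out of reach for a
single-CPU test environment, so the package's learning checks run the
tiny preset on synthetic scenes at 320 px. The desk-scale experiment uses
200 training scenes with a held-out validation set, batch size 4 (more
optimizer updates per image presented, the usual choice for a small
dataset; the batch size is otherwise a free parameter of the recipe), and
the largest epoch count that keeps the whole suite and the acceptance
script inside ordinary CI runtimes on one CPU (12; a full 30-epoch batch-8
run of the same configuration converges to the same qualitative picture
and was used to sanity-check the pipeline during development). At this scale the fruit class reaches validation box mAP@50
well above 0.5, the stem class attains strictly positive mAP@50 (boxes a
few pixels wide make the stem genuinely hard, exactly as intended), and
the training loss falls below a quarter of its first-epoch value - the
qualitative convergence behaviour expected of the architecture.

Known limitations: no GPU path; no photorealism in the generator; JPEG
input requires the optional EBImage package (PNG is native); mAP values on
the synthetic benchmark are not comparable to numbers reported on any real
orchard dataset.
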