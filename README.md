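# orchardseg

Instance segmentation for two-class orchard imagery — **fruit** (apple)
and **stem** — built as a self-contained R package. It targets the vision
component of automated fruit handling: locating every fruit and its thin,
easily-occluded stem as pixel-accurate instances in RGB images.

The detector is a single-stage anchor-free network with mask prototypes
whose backbone downsampling stages are **ghost bottlenecks** and whose
neck carries **global attention modules**:

* A *ghost module* produces `c2/r` output channels with a primary 1×1
  convolution and generates the remaining `c2·(r−1)/r` "ghost" channels
  with cheap 3×3 depthwise convolutions of the primary output,
  concatenating both — for a 16→32-channel 3×3 stage this costs 400
  weights instead of 4608. A *ghost bottleneck* stacks two ghost modules
  around an optional stride-2 depthwise downsampling and a
  squeeze-and-excitation gate `S = σ(W₂·ReLU(W₁·GAP(X)))`, with an
  identity or depthwise+1×1 shortcut.
* A *global attention module* applies channel attention
  `A_c = σ(W₂·SiLU(W₁·GAP(X)))`, `X_c = X ⊙ A_c`, followed by spatial
  attention via two 7×7 convolutions,
  `A_s = σ(W₄·SiLU(W₃·X_c))`, `X_s = X_c ⊙ A_s`.
* The head predicts, per grid cell at strides 8/16/32, a 16-bin
  distribution per box side (decoded by softmax expectation), class
  logits, and 32 mask coefficients combined with stride-8 prototype maps.

Training uses task-aligned assignment and the four-component loss
(CIoU box + BCE classification + distribution focal + prototype mask
BCE) under SGD with momentum 0.937, weight decay 5·10⁻⁴ and initial
learning rate 0.01; evaluation reports COCO-style precision, recall,
mAP@50 and mAP@50–95 for boxes and masks, per class and overall. Every
numerical primitive — convolutions, batch norm, backpropagation, the
optimizer — is implemented inside the package (R with single-precision
C++ kernels), so the whole pipeline runs and is tested without any deep
learning framework.

A built-in synthetic orchard-scene generator (shaded elliptical fruits,
one thin curved stem each, exact polygon ground truth, varied backgrounds
and illumination) makes every stage testable end-to-end without any
external dataset.

## Worked example

```r
library(orchardseg)

# 1. generate a small synthetic dataset and split it 70/20/10
scenes <- generate_scenes(20, scene_config(image_size = 320), seed = 1)
sp <- split_dataset(scenes, split_fractions(), seed = 1)
lengths(sp[c("train", "test", "validation")])
#>      train       test validation
#>         14          4          2

# 2. build and train the desk-scale ("tiny") model
set.seed(1)
model <- build_model(model_spec(preset = "tiny", input_size = 320L))
res <- train_model(model, sp$train, sp$validation,
                   train_config(epochs = 5, batch_size = 4, seed = 1),
                   eval_map = FALSE)
round(res$curves$total, 2)
#> [1] 32.43 28.07 26.40 25.68 25.17

# 3. segment an image and evaluate against ground truth
dets <- lapply(sp$test, function(s) segment_image(res$model, s$image))
evaluate_detections(dets, sp$test)
#> == box ==
#> class    precision    recall    mAP@50 mAP@50-95   n_gt
#> all          0.003     0.125     0.001     0.000     16
#> apple        0.006     0.250     0.002     0.001      8
#> stem         0.000     0.000     0.000     0.000      8
#> ...
```

The training loss falls from the first epoch onward, but five epochs on
14 images is a pipeline smoke run, not a trained model — its mAP is still
essentially zero. The real desk-scale experiment (200 scenes, 12 epochs;
run by the acceptance script below) reaches validation box mAP@50 of 1.00
for the fruit class and about 0.85 for the stem class, with the training
loss ending near a fifth of its first-epoch value. `segment_image()`
returns one detection per instance: class id, confidence, pixel box, and
a binary mask mapped back to the original raster.

A command-line front-end with the same functionality is installed as
`exec/orchardseg` (subcommands `generate`, `split`, `train`, `predict`,
`eval`; every run writes a provenance record with its configuration hash
and seed).

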