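Package: orchardseg
Title: Ghost-Bottleneck and Global-Attention Instance Segmentation for Fruit and Stem Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained instance-segmentation stack for two-class
    (fruit, stem) orchard imagery. Implements a YOLOv8-style anchor-free
    detector with mask prototypes whose backbone downsampling stages are
    ghost bottlenecks (cheap depthwise "ghost" features concatenated to a
    reduced primary convolution, with squeeze-and-excitation gating) and
    whose neck carries global attention modules (sequential channel and
    spatial sigmoid gating). Includes readers and writers for
    YOLO-segmentation polygon labels and COCO instance JSON, a synthetic
    orchard-scene generator with exact ground truth, task-aligned target
    assignment with CIoU, distribution-focal, classification and mask
    losses, an SGD training loop, greedy NMS decoding with prototype mask
    assembly, and COCO-style precision/recall/mAP evaluation for boxes and
    masks. All network primitives are implemented from first principles in
    C++ (im2col + BLAS convolutions) with hand-derived backpropagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
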