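---
title: "Detecting clue cells with context-aware attention: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting clue cells with context-aware attention: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Bacterial vaginosis is diagnosed in part from the presence of *clue cells*:
vaginal epithelial cells coated with adherent Gardnerella bacteria. In
fluorescence microscopy the two cell classes share size and shape almost
completely; what separates them is microscopic — clue cells show a fuzzy,
granular edge and a punctate surface texture from the bacterial coating,
while normal epithelial cells have smooth boundaries and uniform interiors.
Screening additionally suffers from severe class imbalance: most cells, and
most images, contain no clue cells at all. A useful detector therefore has
to be sensitive to weak high-frequency cues and robust to imbalance, and a
useful evaluation has to score what the clinic cares about: whether an
*image* (and ultimately a patient) is flagged, not just whether individual
boxes overlap.

`cayolo` implements that pipeline end to end in R: two feature-enhancement
blocks (CAM and SGAM) inserted into a compact single-stage detector, a
focal-loss-enhanced objective, a synthetic scene generator that reproduces
the phenomenology above, image-level and object-level evaluation, and
paired statistical comparison of detectors.

## The attention blocks

Feature maps in this package are arrays of dim `c(H, W, C)`.

**CAM (context-aware module).** A 1×1 convolution scores spatial context;
a softmax over the `H*W` positions of each channel turns the scores into a
spatial probability distribution, which reweights the input elementwise
(`Xw`). A bottleneck transform (1×1 conv → layer normalisation over the
channel axis → 1×1 conv → sigmoid) gates `Xw` onto itself, and the result
is added back to the input. The block is residual: output − input is
exactly the enhancement term, so an untrained CAM perturbs features only
mildly and a zero input passes through unchanged.

Two design points were genuinely open and are fixed here as follows:

* *Softmax axis.* The score map is normalised over the spatial positions
  within each channel. The block's role is to model where on the feature
  map contextual evidence (bacterial texture) lives, and per-channel
  spatial normalisation is the established convention for global-context
  blocks of this family. Classical global-context blocks pool by a matrix
  product instead of the elementwise product used here; the elementwise
  wiring follows the block description this package implements, and the
  alternative can be built from the same primitives if wanted.
* *Transform bottleneck.* `conv_a` reduces channels by ratio 4 and
  `conv_b` restores them; layer normalisation acts over the bottleneck
  channels at each position.

**SGAM (shuffle global attention mechanism).** Channel attention first:
the channel vector at every spatial position passes through two fully
connected layers (squeeze to `C/r` with ReLU, restore to `C`) and a
sigmoid, giving per-position channel weights `Ac` in (0, 1); the input is
multiplied by them. Spatial attention second: two 7×7 convolutions (the
wide kernel is a deliberate design element — cell contours are large
structures) with ReLU and batch normalisation between them and a sigmoid
at the end give the map `As`, which is *channel-shuffled* before gating.
The shuffle (reshape to `g` groups, transpose, flatten) mixes attention
across channel groups and is a pure permutation — exhaustively tested as
such. The activation order inside the spatial branch is implemented
exactly as composed above (ReLU before batch normalisation), even though
the reverse order is more common in backbones; fidelity to the block
definition wins over convention here.

Unspecified hyper-parameters, fixed once: reduction ratio `r = 4` for both
attentions (bottleneck `max(1, floor(C/r))`), shuffle groups `g = 2`,
both configurable and validated (`g` must divide `C`). Batch
normalisation uses per-sample spatial statistics during training — images
are processed one at a time on CPU, so the sample's `H*W` positions play
the role of the batch — and identity-initialised running statistics at
inference, which keeps single-image oracle tests deterministic.

## The objective

Classification is per-anchor, per-class binary cross-entropy *plus* a
focal term (the focal term augments BCE rather than replacing it; a
`focal_only` switch exists for ablation):

* `l_cls_enhanced = l_bce + l_fl`, with
  `l_fl = -alpha_t (1 - p_t)^gamma log(p_t)`.
* `gamma = 1.5` by default — the value at which sensitivity and F1 peak
  in the sensitivity analysis this package follows; `gamma = 0`,
  `alpha = 1` reduces the focal term exactly to BCE (tested to 1e-9).
* `alpha` comes from inverse class frequency in the training set,
  normalised to sum to the number of classes so that balanced data gives
  unit weights. The weight applies to positive entries; negative entries
  keep weight 1 (the normalised weights may exceed 1, so the classical
  `1 - alpha` negative weighting is not meaningful here). The weights are
  computed once from the training set and then held fixed.

Box regression is CIoU plus distribution focal loss (DFL): each box side
is predicted as a discrete distribution over 16 bins and decoded by
expectation; the DFL cross-entropy targets the two bins bracketing the
continuous distance. The CIoU gradient used in training is fully analytic
(including the dependence of the aspect-ratio weight on the box) and is
verified against finite differences.

Reductions: classification terms average over all anchor-class entries,
box terms over assigned positives; the total is the exact sum
`l_cls_enhanced + l_ciou + l_dfl`. Probabilities are clamped at `1e-7`
before logarithms. No component weighting is applied — the composition is
kept as the plain sum it is defined as; this is a fidelity choice, not a
tuning choice.

## The detector

A compact anchor-free YOLO-style assembly: strided-convolution backbone,
PAN-style neck (top-down then bottom-up fusion), and decoupled 1×1
classification / regression branches at strides 8, 16, 32. Inputs are
square multiples of 32 (512 default; the `tiny` preset defaults to 256).
SGAM insertion follows the two named configurations — `"1_layer_P5"`
(one block after the P5 neck output; the better-performing placement) and
`"3_layers_P345"` — plus `"none"`; CAM defaults to all three neck
outputs, configurable, since the blocks live in the neck by design and
the exact nodes were an open choice.

Target assignment is static and deterministic: each ground-truth box is
routed to the pyramid level matching its longer side (`(0, S/8]`,
`(S/8, S/4]`, `(S/4, ∞)` for input side `S`), claims anchors whose
centres fall inside it within 2.5 strides of its centre, loses contested
anchors to the smaller box, and falls back to the single closest anchor
if it claimed none. A task-aligned dynamic assigner is the convention in
this detector family, but its targets move with the predictions; at
CPU scale (batch-of-one accumulation, tens of epochs) the static
assignment is more stable, exactly reproducible, and cheaper — this is a
recorded deviation, not an oversight. The classification head bias is
initialised to a 1% positive prior, the standard stabiliser for rare
positives under focal-style losses.

Weight initialisation is random (He-scaled); no pretrained weights are
loaded anywhere.

## Training protocol

* **Patient-level split**: patients (not images) are shuffled into an
  80% pool / 20% test split, then the pool into 70% train / 30%
  validation, so no patient leaks across subsets.
* **Search**: random search over the grids
  lr ∈ {1e-4, 5e-4, 1e-3, 5e-3, 1e-2}, batch ∈ {16, 32, 64},
  weight decay ∈ {0, 5e-4, 1e-5, 1e-4, 1e-3}, 20 trials, selected by
  validation F1 (clue class, conf 0.25, IoU 0.5). The shipped defaults —
  lr 1e-3, batch 64, weight decay 5e-4 — are the selected optimum of that
  search protocol; on CPU a smaller batch (8) is the practical choice and
  batches are accumulated per image.
* **Optimiser**: Adam, constant learning rate by default (no schedule is
  part of the stated protocol; a cosine option is available in `fit()`),
  decoupled weight decay on convolution weights only.
* **Early stopping**: patience 50 epochs on validation F1 (the protocol
  states the strategy but not the patience); the returned checkpoint is
  the validation-F1 maximum, ties to the earlier epoch.
* **Augmentation** (training set only): horizontal flip 0.5, rotation
  ≤ 10°, scale ±10%, translation ±10%, shear ≤ 2°, mosaic on until the
  final 10 epochs, MixUp 0.1, Copy-paste 0.1. The kinds are stated by the
  protocol; the probabilities follow detector-family convention and sit in
  `augment_params()`. Boxes are corner-transformed, clipped, and dropped
  below 25% visibility — augmented boxes can never leave the canvas
  (property-tested).

## The synthetic world

The generator states one fixed world per preset and the tests live in it.

* `"default"`: 512 px canvas, 3–8 cells, clue fraction 0.15 (clue cells
  rare, echoing the roughly 1:4 positive-image ratio of clinical
  screening data), clue edge roughness 0.10 (band-limited angular
  perturbation of the boundary radius, harmonics 6–14), punctae density
  0.015 px⁻² on clue cells vs 0.0008 on epithelial, background noise
  0.02, overlap allowed to IoU 0.3.
* `"easy"`: the deliberately separable world for CPU-scale end-to-end
  tests — 256 px, balanced classes, roughness 0.18, punctae 0.035 vs 0,
  no overlap.

Size and shape distributions are identical for both classes *by
construction*, so nothing but edge and texture can separate them;
`difficulty_profile()` certifies this (size/intensity AUC ≈ 0.5, edge
statistic AUC ≫ 0.5 under the defaults, collapsing to ≈ 0.5 when both
cues are switched off). What the generator does **not** emulate: staining
chemistry, optics (PSF, vignetting), cell clumps with shared cytoplasm,
debris, or any photorealistic rendering of bacteria. A green test on this
world shows the pipeline can exploit edge/texture contrast under
imbalance; it does not certify clinical performance.

The image-level ground-truth label uses the same rule as evaluation: an
image is positive when clue-cell box area exceeds 20% — strictly — of
total clue + epithelial box area. The rule is applied to ground-truth
boxes for truth and to predicted boxes (above the confidence threshold)
for predictions; box areas stand in for cell areas because boxes are what
the detector emits.

## Evaluation and statistics

Image level: SEN/SPE/ACC over the 20%-rule labels. Object level:
confidence-ordered greedy one-to-one matching at IoU ≥ 0.5 (the threshold
is a recorded convention), F1 on the clue class by default. Metrics with
empty denominators are reported as `NA` and never silently zero. ROC/AUC
uses a tie-grouped trapezoid (equal to the Mann–Whitney statistic with
half tie credit, tested to 1e-9); PR/AUPRC uses the interpolation-free
step rule.

`mcnemar()` defaults to the continuity-corrected chi-square — with the
published discordant counts (34, 13) it reproduces p ≈ 0.0035 — and
offers the exact binomial form for small counts.
`bootstrap_accuracy_diff()` resamples images with replacement (10,000
replicates, percentile interval by default; neither count nor method is
fixed by the protocol it follows) and reports percentage points. Coverage
of the 95% interval is property-tested at 90–99% over 200 simulations.

## Numerical and engineering choices

* Convolutions run through compiled im2col/GEMM kernels (RcppArmadillo)
  inside a ~300-line reverse-mode autograd; everything else is plain R.
  The backward pass recomputes im2col rather than caching it — memory
  stays flat and the recompute is cheaper than shipping the column
  matrices through R.
* Every block's forward pass is checked against an explicit-loop
  straight-line oracle (tolerance 1e-5 or better), and every gradient
  path — conv, attention blocks, classification loss, CIoU, DFL, and the
  full model — against central finite differences.
* Scaled-down sizes in tests: the `tiny` preset (8/16/24/32/48 channels)
  at 256 px trains in minutes on one CPU; the end-to-end acceptance run
  uses 200 training images and ≤ 30 epochs with flip-only augmentation,
  because compound augmentation pays off over hundreds of epochs on real
  data, not over twenty on an easy synthetic world.
* Known limitations: no GPU path, no dynamic assigner, no multi-IoU mAP,
  single-image batch statistics in BN, and the synthetic world's gap to
  clinical imagery noted above. The dataset-dependent benchmark numbers
  of the underlying study (trained on private clinical data) are outside
  what this package can or tries to reproduce.
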