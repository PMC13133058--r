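---
title: "Appearance + venation fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Appearance + venation fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Leaf photographs carry two largely independent identity signals. The
*appearance* signal — pigment, surface texture, blade outline — is easy to
photograph but drifts with illumination, season and leaf age. The
*venation* signal — the branching topology of the vascular network — is
anatomically stable and species-characteristic, but extracting it requires
image processing and discards the appearance cues that separate
visually-similar species. `veinfuse` implements a two-stream classifier
that keeps both: a frozen convolutional backbone embeds the RGB photo
(MobileNetV2, 1,280 pooled features), a second frozen backbone embeds the
binary vein map rendered through a jet colour mapping (DenseNet121, 1,024
pooled features), the two global-average-pooled vectors are concatenated
into a 2,304-dimensional representation, and a small trainable head
(dense 128 ReLU with L2 `1e-4`, dropout 0.5, dense softmax) performs the
classification under label-smoothed (`eps = 0.01`), class-weighted
cross-entropy with Adam at learning rate `1e-5` and batch size 16.

Four single-stream baselines are provided for comparison: MobileNetV2 on
RGB alone, DenseNet121 and EfficientNetB0 on jet-mapped vein maps alone,
and DenseNet121 on a *fused image* whose red channel is replaced by the
vein map while green and blue keep the appearance.

Backbones are always frozen. The shipped default is `random-frozen`:
seeded He-normal convolution weights with identity batch-norm. Random
frozen convolutional features are well-studied as fixed projections —
they preserve oriented-texture and colour statistics well enough for a
linear probe, which is what the trainable head is. `pretrained-frozen`
accepts user-supplied weight lists with the same layout; fine-tuning
backbones is deliberately unsupported. The head's hidden layer is
Glorot-uniform; the output layer starts at zero, the standard choice for
a linear probe on frozen features: predictions start exactly uniform and
every logit that develops is learned signal rather than initialization
noise.

## The vein-extraction pipeline

`extract_veins()` composes eight classical stages; every free parameter
lives in `vein_pipeline_config()`. Stage by stage, with defaults and
units:

1. **Grayscale** — BT.601 luminance (`0.299 R + 0.587 G + 0.114 B`).
2. **Leaf mask** — Otsu threshold (exhaustive 256-bin scan of the
   between-class variance), foreground chosen as the side with the lower
   border occupancy (the blade is central, the background touches the
   frame), largest connected component, morphological closing with an
   elliptical element (7 px), hole filling. When several thresholds
   attain the maximal variance — typical for histograms with an empty
   gap between modes — the centre of the plateau is returned; a
   first-argmax rule would sit at the gap's edge and split bimodal
   images asymmetrically.
3. **CLAHE** — clip-then-redistribute contrast-limited adaptive histogram
   equalization, 8×8 tiles, relative clip limit 2, bilinear blending
   between tile mappings. With one tile and an unbounded clip limit it
   reduces exactly to plain histogram equalization, which the tests
   exploit as an oracle.
4. **Homomorphic filter** — `log(1 + I)`, 2-D FFT, transfer function
   `H = B + A(1 - exp(-k D²/D0²))` (A = 1.5, B = 0.5, k = 1, D0 = 30
   cycles/image), inverse FFT, `expm1`, min–max normalization. `H` equals
   `B` at zero frequency and approaches `A + B` at high frequency, so
   reflectance detail is amplified relative to the illumination field.
5. **Gabor bank** — orientations {0, 30, 60, 90, 120, 150}°, kernel sizes
   {15, 21} px, wavelength λ = 8 px, envelope σ = 4 px, aspect γ = 0.5,
   phase ψ = 0; the pixel-wise *maximum* response over the bank is kept,
   which makes veins bright regardless of their raw polarity and is
   approximately invariant to rotating the input by half the orientation
   step.
6. **Weighted fusion** — `0.5 · homomorphic + 0.5 · Gabor` (equal weights),
   optional bias 0.
7. **Selective unsharp masking** — `I + α(I − blur(I))`, α = 1, Gaussian
   σ = 2 px, applied only on the eroded leaf interior so no halo forms at
   the blade boundary.
8. **Binarization and cleanup** — percentile stretch (2nd–98th percentile
   to range ends), adaptive mean threshold (window 25 px): a pixel fires
   when it exceeds its neighbourhood mean by more than C = 5 (0–255
   scale). Marking pixels *above* `mean + C` is the only sign convention
   under which a flat region stays silent and a bright line fires;
   near-constant inputs short-circuit to an empty mask. The mask is then
   intersected with the leaf interior, components under 30 px are
   removed, an elliptical 3×3 opening and a 3×3 median follow.

Structuring elements are true discrete Euclidean discs (a 3×3 "ellipse"
is a cross, as in OpenCV). This matters: with a full 3×3 box the opening
erases 3-px-wide strokes — the very structures the pipeline exists to
keep — and recovery of synthetic veins collapses.

All neighbourhood operations use reflect padding. The pipeline ends at
the median filter; `thin_mask()` (Zhang–Suen) is available behind an
explicit `thin` flag but off by default, since the flow itself specifies
no thinning operator.

## The synthetic-leaf generator

Real paired RGB/vein datasets cannot ship with the package, so
`generate_leaf()` renders parametric leaves with exact ground truth. An
archetype fixes blade shape (ovate, lanceolate, round, lobed; serration
as a radial high-frequency term), base HSV colour with per-leaf jitter,
and a venation recipe (midrib, secondaries at a given angle and spacing,
optional tertiaries; anti-aliased strokes re-binarized at 0.5 coverage).
Backgrounds are uniform white, matching the white-background convention
of curated leaf datasets. Secondary veins are drawn at the full
configured stroke width (only tertiaries taper): sub-3-px strokes cannot
survive a 3×3 opening, which is a documented limitation of the cleanup
stage, not of the generator. Veins are painted into the RGB image as a
+0.12 value-channel offset — visible, as on a real leaf, but small
enough that archetypes differing only in venation remain
indistinguishable in mean colour (the property the two-branch comparison
needs).

Datasets group leaves into *instances* (one physical leaf) rendered
several times with small rotation and illumination jitter;
`stratified_group_split()` keeps every instance in a single subset
(largest-remainder apportionment of instance groups per class), which is
what prevents leakage between train and test.

What the generator does **not** emulate: specular highlights, shadows,
background clutter, disease, 3-D curvature, camera noise. Passing tests
on synthetic leaves therefore demonstrates correctness of the machinery
and the relative behaviour of the model variants, not field-ready
accuracy on photographs.

## Imbalance handling

Classes with fewer than 800 samples (strictly fewer) receive the
*strong* augmentation tier — rotations to ±40°, flips, shifts to 10%,
elastic distortion (α = 40 px, σ = 6 px), Gaussian noise with variance in
[0.005, 0.02] — while majority classes receive the *light* tier
(±15°, flips, 5% shifts). Class weights are balanced inverse frequencies
`w_c = N/(K·N_c)`, so the average sample keeps weight 1 exactly.

Because the backbones are frozen, the features of a fixed image never
change between epochs; re-running augmentation every epoch would only
re-extract identical features. Augmented views are therefore
materialized once before feature extraction (`augment_rounds` in the
config), a compute-bounded equivalent of online augmentation under a
frozen encoder. Geometric transforms are applied synchronously to the
paired vein mask (nearest neighbour); photometric noise never touches
the mask.

At these small training sizes the class-weighting effect is measured one level below
argmax: with ~5 minority training samples the weighted run raises the
predicted minority probability mass several-fold while both runs can
remain on one side of the 0.5 decision line, so the suite asserts the
probability-mass ordering (and a non-strict recall ordering) rather
than a strict recall inequality.

## Problem sizes and training lengths used by the checks

The test-suite and the acceptance script use sizes chosen to exercise
every code path while staying quick to run: 30 synthetic leaves (224×224, vein width
3 px, spacing 25 px) for vein recovery; a 3-class, 210-leaf dataset
split 150/30/30 for the end-to-end smoke test, trained with the default
configuration (50 epochs, batch 16, Adam 1e-5); and three 120-leaf
seeds for the venation-only comparison. For that comparison the head is
given `max_epochs = 300`: the default 50-epoch budget is calibrated for
datasets two orders of magnitude larger, and at ~100 training samples
the same learning rate simply needs more passes to converge — the
backbones stay frozen and every other hyperparameter is unchanged.

## Numerical conventions

* Images are plain numeric arrays; both unit-float and 8-bit ranges are
  accepted and preserved. Pipelines work internally in float.
* Jet colour mapping restricted to a binary domain yields exactly the two
  jet endpoints — (0, 0, 128) for background, (128, 0, 0) for vein — by
  construction.
* All randomness is seed-parameterized (`rng_seed` arguments evaluate
  under a private RNG stream and restore the caller's state), so every
  generator, split, augmentation and training run is reproducible
  bit-for-bit on one platform.
* Convolutions inside the backbones run in float32 through im2col + GEMM
  kernels (Rcpp/Armadillo); 1×1 convolutions shortcut to a plain matrix
  product.
* Adam uses β₁ = 0.9, β₂ = 0.999, ε = 1e-7; early stopping restores the
  best-validation-loss head; learning-rate reduction on plateau uses
  factor 0.5 with patience 5 by default.

## Known limitations

* Vein maps thinner than the 3×3 opening's support are partially erased;
  lower `min_object_area`/`opening_se` for fine venation at the cost of
  more speckle.
* Random-frozen features are weaker than ImageNet-pretrained ones; the
  smoke tests demonstrate learnability and the venation/appearance
  dissociation, not production accuracy.
* The classifier consumes the vein masks carried by the records —
  generator ground truth in the tests; on photographs the extracted maps
  inherit any extraction error.
* EfficientNetB0's squeeze-excitation gates attenuate random-weight
  activations noticeably; the variant is provided for architectural
  completeness and dimension checks.
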