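---
title: "EHFF: model, design choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EHFF: model, design choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The segmentation problem

Multi-modal brain MRI (t1, t1ce, t2, flair) is segmented into three nested
tumor regions derived from the standard label convention — enhancing tumor
(ET, label 4), tumor core (TC, labels 1 and 4), and whole tumor (WT, labels
1, 2 and 4). The regions overlap by construction (`ET ⊆ TC ⊆ WT`), so the
network predicts three independent sigmoid channels rather than one softmax
partition, and agreement is measured per region with the Dice similarity
coefficient `2|S∩G|/(|S|+|G|)`.

## Architecture

**Encoder.** A 7×7×7 stride-2 stem maps the four modalities to the base
width (48) at half resolution, followed by a channel-wise layer
normalisation. Four stages each apply one adaptive feature learning (AFL)
block and a down-sampler. An AFL block runs two residual iterations of
macro-perception — a depthwise 7×7×7 convolution providing a wide receptive
field — and micro-focus — a voxel-wise 1×1×1 pair (C → 4C → C, GELU
between) refining channel interactions — with a layer norm in front of each
sub-step. Down-samplers are 2×2×2 stride-2 convolutions that double the
width; the fourth stage keeps 1/16 resolution and doubles channels with a
1×1×1 map, giving the pyramid 48/96/192/384/768 channels at scales 1/2,
1/4, 1/8, 1/16, 1/16.

**Skip projections.** Each pyramid level passes through a shape-preserving
residual block of two depthwise-separable 3×3×3 units (depthwise + 1×1×1 +
layer norm + GELU), yielding Z1–Z5.

**Hierarchical feature weighting (HFW).** Per level: a 1×1×1 compression to
a narrower refinement width, two residual refinement units (two dense 3×3×3
convolutions with layer norms, closed by a 1×1×1), an elementwise learnable
weighting `E + E·R` with R a per-channel vector optimized by
backpropagation, one final refinement stack whose closing 1×1×1 is the
expansion back to the level width. Residual bridges around each unit keep
gradients healthy.

**Primary decoder.** Starting from the weighted Z5, the ladder fuses one
level at a time (concatenation with the weighted skip, 1×1×1 reduction,
layer norm, GELU, separable residual block), up-sampling ×2 with 2×2×2
transpose convolutions between levels; the Z5→Z4 step preserves resolution
because both live at 1/16. The terminal step concatenates the stem feature,
fuses, and a final transpose convolution restores full resolution at 48
channels (P).

**Hierarchical feature retention (HFR).** An auxiliary decoder that
projects every Zi to 48 channels with a 1×1×1 map, up-samples trilinearly
to full resolution (repeated ×2, half-pixel convention) and sums the five
maps (Q). The head computes `sigmoid(conv1x1(P·∂ + Q·(1−∂)))` with
`∂ = 0.8`; predictions binarize at 0.5 and are re-encoded to labels by
nesting inversion (ET→4, TC∖ET→1, WT∖TC→2).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `base_width` | 48 | stem width; all pyramid widths are multiples of it |
| `lk_kernel` | 7 (voxels) | macro-perception kernel extent; odd so "same" padding is symmetric |
| `mf_expansion` | 4 | micro-focus hidden multiplier, the usual transformer-MLP ratio |
| `depths` | 1,1,1,1 | AFL blocks per stage (each internally two-iteration) |
| `hfw_hidden` | 35/71/97/193/399 | HFW compression widths of the reference model (see calibration) |
| `fusion_coefficient` | 0.8 | convex weight of the primary decoder in the terminal fusion |
| learning rate | 0.001 | Adam, batch size 1 |

The published trainable-parameter total (44,053,394) is treated as a
binding structural constraint. With the architecture above fixed, the five
HFW compression widths are the only remaining free widths; an exact-integer
search (`tools/calibrate_params.R`) selects the solution closest to the
half-width heuristic that reproduces the total exactly. Two related design
choices make that total reachable at all: convolutions that feed directly
into a layer normalisation carry no bias (the norm's shift makes a bias
redundant), and the final HFW stack's closing 1×1×1 *is* the expansion back
to the level width rather than an extra width-preserving projection.

## Choices where the design was genuinely open

- **Macro-perception kernels are depthwise.** Dense 7×7×7 kernels at width
  768 would contribute billions of parameters; depthwise kernels match the
  lightweight large-kernel design the architecture builds on, and a
  `mp_form = "dense"` switch exists for small configurations.
- **HFW operates in a compressed width**, and the weighting vector R has
  the length of the compressed feature E it multiplies (initialised
  U(0, 1)). Full-width refinement stacks at 768 channels would alone exceed
  the entire parameter budget; the compressed reading also matches E's role
  as a "compression refined" feature. The two refinement loops use separate
  weights (loop unrolling), not shared ones.
- **Skip fusion is concatenation + convolution block**, the convention of
  the U-Net family this architecture is benchmarked against; the residual
  variant would force equal widths everywhere.
- **Decoder ladder direction.** The level recursion is read deepest-first
  (Z5 → Z1), the only direction consistent with progressive up-sampling and
  the printed shapes.
- **Up-sampling operators.** Transpose convolutions (2×2×2, stride 2) in
  the primary decoder, where learnable upsampling earns its parameters;
  plain trilinear interpolation in the auxiliary HFR decoder, which is
  deliberately cheap.
- **Training loss.** Soft Dice over the three region channels
  (`eps = 1e-5`), the natural choice for overlapping-region sigmoid
  outputs; a Dice + binary-cross-entropy variant is available
  (`loss = "dice_ce"`).
- **Stem normalisation** is a single layer norm terminating the stem,
  distinct from the norms inside the first AFL block; `stem_norm = FALSE`
  disables it.

## Numerical conventions

- Layer normalisation is computed per voxel over channels with
  `eps = 1e-6`; an all-zero input maps to zero (the centered value is zero
  before scaling).
- GELU is exact (`x·Φ(x)`), not the tanh approximation.
- Weights initialise from a truncated normal (sd 0.02, cut at ±2 sd),
  biases and norm shifts at zero, norm gains at one; everything is seeded
  from the configuration, and forward passes are bit-reproducible on a
  fixed machine.
- Dice conventions: both masks empty → 1 (agreement on absence), exactly
  one empty → 0. Binarization threshold 0.5.
- Across-fold spread: `aggregate_folds()` reports both the population
  standard deviation and the population variance of the per-fold means.
- Sliding-window inference uses 0.5 overlap with mean blending; volumes
  smaller than the window are zero-padded and cropped back.
- Preprocessing z-scores each modality over its nonzero voxels (sample
  standard deviation); center crop/pad to a multiple of 16 — the extent
  divisibility the two-plus-four halvings require.

## The phantom generator

`generate_phantom()` emulates the structure of a labeled multi-modal case:
three nested ellipsoids (enhancing core, radius 7; core shell, 13; edema
shell, 20 voxels by default in a 64³ volume, center jittered ±3 voxels)
embedded in homogeneous healthy tissue, rendered through a fixed modality ×
tissue-class contrast table that mimics the qualitative appearance of the
four sequences (t1ce-bright enhancement, flair-bright edema, t2-bright
core) with additive Gaussian noise (σ = 0.1 against contrasts of order 1).
Labels follow the 0/2/1/4 shell convention so the derived regions nest by
construction.

The phantom reproduces the *format and label semantics* of real data, not
its difficulty: real tumors are heterogeneous, irregular, and imaged with
bias fields and anatomy the phantom lacks. Passing the phantom-based tests
therefore shows that the architecture, gradients, optimizer and evaluation
pipeline are correct and can drive the training error down — it says
nothing about segmentation accuracy on clinical data, which requires the
real cohort and GPU-scale training and is out of scope here.

## Problem sizes used by the test-suite

Unit tests run a narrow model (base width 4) on 16³–32³ volumes. The
training check runs base width 12 on eight 64³ phantoms for at most 200
Adam steps with early stopping once every region's training Dice exceeds
0.85 (reached around step 120 at the default seeds). The structural checks
(parameter count, shape schedule) use the full reference width. These sizes
were chosen so the whole suite runs comfortably on a single CPU in double
precision.

## Known limitations

- Single-volume batches only (batch size 1 is also the published protocol).
- CPU, double precision; no GPU path, no mixed precision.
- No data augmentation or learning-rate schedule by default (neither is
  specified for the original training runs).
- Post-processing (connected-component cleanup), test-time augmentation and
  ensembling are out of scope.
- The up-sampling chain assumes power-of-two scale relations, hence the
  multiple-of-16 input constraint; arbitrary shapes go through the
  sliding-window path.
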