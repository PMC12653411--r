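---
title: "GAAD-U-Net: model, metrics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GAAD-U-Net: model, metrics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

White blood cell (WBC) segmentation assigns every pixel of a stained blood
smear image to one of three classes — background (0), cytoplasm (1), or
nucleus (2). The hard cases are low-contrast cytoplasm boundaries, touching
or overlapping cells, red-blood-cell clutter, and stain/brightness
variability between laboratories. `gaadunet` implements a gated,
attention-augmented Double U-Net (GAAD-U-Net) for this task, along with the
standard evaluation statistics, a soft Dice training objective, a synthetic
smear generator, and a CPU training loop.

## The model

GAAD-U-Net is a two-phase (double) encoder–decoder network.

**Phase 1** uses a VGG-19-style encoder: four blocks of 2/2/4/4
convolutions (3×3, batch norm + ReLU) with 2×2 max pooling after the first
three blocks, so the fourth block's output sits at 1/8 of the input
resolution with 512 channels at the reference widths (64/128/256/512). For
a 224×224 input the bottleneck is therefore 28×28; for 512×512 it is 64×64.
The bottleneck applies, in order:

1. **Attention-augmented convolution (AAC).** The output concatenates a
   standard 3×3 convolution producing `out_channels − dv_total` channels
   with a multi-head self-attention branch producing `dv_total` channels
   (followed by a 1×1 output projection). Attention logits for query pixel
   $p$ and key pixel $q$ in head $h$ are

   $$\ell_{pq} = \frac{q_p^\top k_q + q_p^\top (r^{row}_{\Delta i} + r^{col}_{\Delta j})}{\sqrt{d_k^h}},$$

   where $r^{row}, r^{col}$ are learnable relative-offset embedding tables
   with $2H-1$ and $2W-1$ entries and $(\Delta i, \Delta j)$ is the spatial
   offset between $q$ and $p$. A softmax over all $H\cdot W$ keys gives
   weights that sum to one per query and head; the weighted sum of value
   projections forms the attention output. The reference configuration uses
   32-dimensional keys and values **in total**, distributed over four heads
   (8 per head) — the `dk_total`/`dv_total` fields make the alternative
   reading (32 per head) a one-line config change.
2. **Gating.** $z = x \odot \sigma(\mathrm{Conv}_2(\mathrm{ReLU}(\mathrm{BN}(\mathrm{Conv}_1(x)))))$
   with 1×1 convolutions squeezing the channels from $C$ to
   $\lfloor C/2\rfloor$ (minimum 1, so odd and unit channel counts do not
   crash) and back. Because the mask is a sigmoid output, $|z| \le |x|$
   elementwise and $z$ keeps the sign of $x$.
3. **ASPP.** Parallel branches — a 1×1 convolution, one 3×3 dilated
   convolution per rate (default 6/12/18, the Double-U-Net convention), and
   a global image-pooling branch — concatenated and projected by a 1×1
   convolution with BN + ReLU.

The Phase-1 decoder has four blocks. The first concatenates the bottleneck
output with the block-4 skip at 1/8 resolution (no upsampling); the
remaining three bilinearly upsample by 2 and concatenate the block-3/2/1
skips. Each block applies two 3×3 conv+BN+ReLU units followed by
squeeze-and-excitation (SE, reduction 8). A 1×1 convolution + softmax head
emits the Phase-1 probability map.

**Phase 2** re-encodes the input image multiplied by the Phase-1
*foreground* ($1 - P(\text{background})$, broadcast over RGB). Its encoder
uses conditional pooling — no pooling in block 1, 2×2 max pooling in blocks
2–4 — with two conv units and SE per block, reaching the same 1/8
bottleneck, which repeats the AAC → gating → ASPP cascade with independent
parameters. Each Phase-2 decoder block concatenates three inputs: the
upsampled features, the Phase-2 encoder skip, and the matching Phase-1
decoder output. The final segmentation concatenates both phase probability
maps (6 channels) and fuses them with a learnable 1×1 convolution +
softmax.

### Choices where the architecture description was open

* **Phase-2 input at inference.** The original formulation multiplies the
  first-stage output with the ground truth, which cannot exist at
  inference. The package gates with the *predicted* foreground by default
  (the Double U-Net convention of multiplying the input by the first
  output) and offers ground-truth gating as a `teacher_forcing` training
  option.
* **Fusion head.** How 6 concatenated channels become 3 is unstated; a
  minimal learnable 1×1 convolution + softmax is used, initialized as a
  pass-through average of the two phase maps (diagonal weights 2, zero
  elsewhere). A randomly initialized fusion layer has to re-learn the
  channel correspondence after the phases converge; with identity-style
  initialization the fused prediction is consistent with the phases from
  the first step, which materially stabilizes short training runs.
* **Deep supervision.** Both phase outputs and the fused map are trained
  with the same soft Dice loss, summed with configurable weights (default
  1/1/1).
* **Decoder widths** default to half the mirrored encoder widths
  (256/128/64/32); the first decoder block consumes the bottleneck plus the
  block-4 skip without upsampling, which is the only arrangement that
  yields four decoder blocks, four skips, and a full-resolution output
  given pooling after encoder blocks 1–3 only.
* **Conv-branch normalization in the AAC.** The concatenated AAC output
  passes through BN + ReLU (`post_norm`, on by default); the branch
  convolutions themselves are bare.
* **Encoder-1 weights** are randomly initialized (He); there is no
  pretrained-backbone download, keeping the package self-contained.
* **SE squeeze bias** is initialized to 1. The squeeze layer sees a
  nonnegative pooled descriptor, so a zero-mean initialization can leave a
  very narrow bottleneck (1–2 units at test widths) entirely in the dead
  half of the ReLU; a positive bias starts every gate path active. At the
  reference widths this is immaterial.
* **Argmax ties** resolve to the lowest class index, for determinism.
* **Stride.** Only stride-1 attention is implemented; nothing in the
  architecture calls for another stride.

## The autodiff engine

No deep-learning framework is part of the package's dependency set;
instead `gaadunet` ships a compact reverse-mode automatic-differentiation
engine: a global tape records each operation's backward closure, and
`ag_backward()` replays it in reverse. Dense kernels (same-padded stride-1
convolution with dilation, 2×2 max pooling, 2× bilinear upsampling, batch
norm, ReLU) are C++ (RcppArmadillo, im2col + GEMM); attention, softmax, SE
and the Dice loss are vectorized R. Every kernel's gradient is verified in
the test suite against central finite differences, and the attention
forward against an explicit double-loop oracle. Batch norm uses batch
statistics (momentum 0.1 running updates) in training mode and running
statistics in evaluation mode, which makes the algebraic-identity tests
deterministic.

## Training

The objective is the multi-class soft Dice loss
$1 - \frac{1}{C}\sum_c \frac{2\sum p_c g_c + \varepsilon}{\sum p_c + \sum g_c + \varepsilon}$
with $\varepsilon = 10^{-6}$, one-hot ground truth, sums taken jointly over
the batch, and an unweighted mean over all three classes. With this
smoothing a class absent from both target and prediction contributes a
soft Dice of 1 (no penalty). Optimization uses Adam (reference recipe:
learning rate $10^{-4}$, batch 4 for 512×512 inputs or 16 for 224×224)
under polynomial learning-rate decay
$\mathrm{lr}(s) = \mathrm{lr}_0\,(1 - s/S)^{0.9}$. All randomness —
initialization, shuffling, augmentation — flows from the single configured
seed, so runs reproduce exactly.

`overfit_benchmark()` is the package's capacity check: a width-reduced
model (widths/4, i.e. 16/32/64/128) trained 200 steps with batch 2 on
eight synthetic 96×96 scenes must memorize them (train DSC > 0.9). For
this small-batch, short-horizon setting a learning rate of $10^{-2}$ is
used — chosen once from a short pre-run comparison of
$10^{-3}/3\cdot10^{-3}/10^{-2}$ at 80 steps, since the reference recipe's
$10^{-4}$ is calibrated for 100–150-epoch runs, not 200-step memorization.

## Evaluation metrics

Per class, one-vs-rest pixel counts give IoU $= \mathrm{tp}/(\mathrm{tp} +
\mathrm{fp} + \mathrm{fn})$ and DSC $= 2\mathrm{tp}/(2\mathrm{tp} +
\mathrm{fp} + \mathrm{fn})$, which satisfy $\mathrm{DSC} =
2\,\mathrm{IoU}/(1 + \mathrm{IoU})$ exactly — the suite asserts this
identity to $10^{-12}$. Accuracy is the joint fraction of correctly
labeled pixels. Surface metrics operate on boundary pixels (class pixels
with at least one 4-neighbor outside the class, the image border counting
as outside), in pixel units on pixel centers (the benchmark datasets carry
no physical spacing):

* **HD95** — the larger of the two directed 95th-percentile
  nearest-neighbor distances, with linear interpolation on the sorted
  distance list;
* **ASSD** — the symmetric mean nearest-neighbor distance.

Aggregation conventions: "mean IoU"/"mean DSC" are unweighted macro means
over all three classes by default (`exclude_background` switches to
foreground-only); HD95/ASSD are computed per foreground class and macro
averaged. Empty-class policy: a class absent from both masks is skipped
from the macro mean; a class absent from exactly one scores 0 overlap and
the image diagonal as surface distance, and the report row is flagged.

## Synthetic scenes and augmentation

`generate_scene()` emulates the structure of stained-smear benchmarks so
every component is exercisable without dataset downloads: elliptical cells
whose dark purple nucleus (a sampled fraction, default 0.45–0.7 of the
cytoplasm radius, kept at least 2 px inside) sits strictly within a pale
violet cytoplasm; a textured pink background; red-blood-cell-like ring
distractors that remain labeled background (the clutter/adhesion failure
mode); per-cell stain jitter; a scene-wide brightness offset (±12%); and
additive Gaussian noise (σ = 1–3% of the dynamic range). Non-overlapping
placement uses rejection sampling and fails with actionable guidance when
the packing is infeasible. Identical spec + seed reproduces a scene bit
for bit, and dataset element `i` always uses `seed + i − 1`.

What the generator does **not** model: the five WBC subtype morphologies,
lobed/multi-part nuclei, partial staining, focus blur, and true cell
overlap with ambiguous boundaries. Passing the synthetic benchmarks
demonstrates that the architecture, gradients, metrics and pipeline are
correct and that the model has the capacity to fit smear-like scenes — it
does not certify accuracy on real microscopy.

The augmentation policy mirrors the training recipe: horizontal flip,
vertical flip, rotation, Gaussian noise, and brightness shift, each firing
independently with probability 0.5; geometric operations apply identically
to image and mask (nearest-neighbor for free angles, so no interpolated
labels), photometric ones to the image only. Rotation defaults to
{90°, 180°, 270°} so masks need no resampling at all; the exact magnitudes
of the photometric operations are not pinned anywhere authoritative, so
σ = 0.02 and ±15% brightness are package defaults, configurable.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script problem sizes are the package's
choices for a laptop-class CPU run: oracle comparisons use grids up to
6×6 (attention) and 16×16 masks / 50-point boundary sets (metrics);
architectural contracts run single full-width forwards at 224×224 and
512×512; learning checks use the width-reduced 96×96 configuration above;
the CLI smoke test runs a 48×48, narrow-width round trip. Scaling any of
these up only costs time.

## Known limitations

* CPU-only and double precision; a full-width 512×512 forward takes on the
  order of two minutes, so the package is a reference implementation and
  test bed rather than a production inference engine.
* Batch-norm running statistics are updated with the biased batch variance
  rescaled by $m/(m-1)$; very small batches give noisy evaluation-mode
  behavior early in training.
* The soft Dice is computed batch-aggregated (sums over the whole batch),
  not per-image averaged.
* No pretrained VGG-19 weights; transfer-learning comparisons are out of
  scope.
* `hd95`/`assd` use exact all-pairs nearest neighbors (chunked); boundaries
  beyond a few tens of thousands of points would want a spatial index.
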