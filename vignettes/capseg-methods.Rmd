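---
title: "Methods: coordinate-attention pyramid parsing for lesion segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coordinate-attention pyramid parsing for lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Medical segmentation targets — lung tumours in CT slices, polyps in
colonoscopy frames, skin lesions in dermoscopy — are often small relative
to the image, have fuzzy boundaries, and sit on noisy backgrounds. Two
failure modes dominate: per-pixel losses saturate when the background
dwarfs the lesion (a model predicting "all background" is >99% accurate on
a lesion occupying <1% of the image), and global pooling discards the
positional information needed to localise small targets. This package
addresses both with a light pyramid-parsing network whose backbone
features are reweighted by coordinate attention, trained with a mixed
Dice + Focal loss.

## Model

**Backbone.** A MobileNetV2-style extractor: stride-2 3x3 stem to 32
channels, then the canonical inverted-residual schedule
(t, c, n, s) = (1,16,1,1), (6,24,2,2), (6,32,3,2), (6,64,4,2), (6,96,3,1),
(6,160,3,2), (6,320,1,1), truncated before the 1280-channel classifier
head. Every convolution under a batch-norm layer is bias-free; blocks use
ReLU6. At the default output stride 8 the stride-2 entries of the 64- and
160-channel stages run at stride 1, and the depthwise convolutions of the
converted stages are dilated — rate 2 for the 64/96 stages, rate 4 for the
160/320 stages — following the standard dilated-network recipe; dilation
adds no parameters, so the stride-8 and stride-16 variants have identical
budgets. For an input side $S$ the deep map side is
$\lfloor (S-1)/8\rfloor + 1$ (60 for 473, 13 for 97).

**Coordinate attention.** Global average pooling is factorised into two
strip pools, $z^h_c(h) = \frac{1}{W}\sum_i x_c(h,i)$ and
$z^w_c(w) = \frac{1}{H}\sum_j x_c(j,w)$. The strips are concatenated along
the spatial axis, squeezed by a shared, bias-carrying 1x1 convolution to
$\max(8, \lfloor C/r\rfloor)$ channels (reduction $r = 16$ by default; the
floor keeps small-$C$ blocks non-degenerate), batch-normalised and passed
through hard-swish (configurable to plain ReLU) — the convention of the
coordinate-attention literature for the unspecified mid-block
nonlinearity. The result is split back into height and width parts,
restored to $C$ channels by two *independent* 1x1 convolutions (the
block diagram shows separate transforms; weight sharing between them is
not indicated), and gated by sigmoids. The output is
$y_c(i,j) = x_c(i,j)\, g^h_c(i)\, g^w_c(j)$, so every output magnitude is
bounded by the input magnitude — a property the tests assert on random
inputs.

One CA block wraps the stem output (32 channels), a second wraps the final
320-channel map. "Before and after backbone feature extraction" admits
another reading (a mid-level shallow map rather than the stem); the
placement is configurable so both can be tried, and the stem reading is
the default.

**Pyramid pooling.** The deep map is adaptively average-pooled to 1x1,
2x2, 3x3 and 6x6 grids; each branch is compressed by a 1x1 convolution to
`deep/4` = 80 channels (so the concatenation doubles the width, the
pyramid-parsing convention), upsampled bilinearly and concatenated with
the deep map itself — 640 channels — then fused by a 3x3 convolution to 80
channels with dropout 0.1 before the classifier. "Fused with the shallow
features" is implemented as this standard concatenation with the deep map;
an option exists to additionally concatenate a mid-level map. No auxiliary
loss branch is used. Bilinear sampling is corner-aligned by default, which
suits the odd "8k+1" geometry of 473 or 97 pixel inputs.

**Parameter budget.** Summing learnable scalars (convolution weights and
biases, normalisation scales and shifts): backbone 1,811,712; stem CA 856;
deep CA 19,900; pyramid branches 103,040; fusion head 460,960; classifier
162 — total 2,396,630 ≈ 2.40 M. The whole-network count equals the sum of
module counts exactly, and disabling both CA blocks removes exactly their
own 20,756 scalars; both identities are tested.

## Loss

$$\mathrm{Mixed} = \lambda\,\mathrm{Dice} + (1-\lambda)\,\mathrm{Focal},
\qquad \lambda = 0.6,$$

with
$\mathrm{Dice} = 1 - (2\sum_i G_iP_i + \varepsilon)/(\sum_i G_i + \sum_i P_i + \varepsilon)$
on the soft foreground probability and
$\mathrm{Focal} = \mathrm{mean}(-\alpha(1-p_t)^\gamma\log p_t)$ on the
clamped true-class probability (natural log, $p_t$ clamped to
$[10^{-7}, 1-10^{-7}]$). Choices where the formulation leaves freedom:

* $\alpha = 0.25$, $\gamma = 2$ — the original focal-loss defaults; both
  exposed in `loss_config()`.
* $\varepsilon = 10^{-5}$ smoothing in numerator and denominator — the
  bare Dice ratio is undefined on empty masks; with smoothing an all-empty
  prediction of an all-empty mask scores loss 0.
* Dice is batch-aggregated (sums over the whole batch) rather than
  averaged per image: for tiny lesions a per-image Dice is dominated by
  quantisation noise; the per-image mode remains available
  (`dice_mode = "image"`).
* "$p$, the probability value predicted by the model" is read as the
  true-class probability $p_t$ (the standard focal-loss reading); a
  foreground-only reading would leave background pixels undefined.

The analytic gradient with respect to the logits (Dice chain plus focal
chain through the softmax) is verified against central finite differences
at relative tolerance $10^{-3}$ in the tests.

## Data pipeline

Masks are single-channel 8-bit rasters with background 0 and target 255,
remapped to {0, 1}; any value ≥ 128 counts as foreground, which tolerates
compression artefacts. Images are resized bilinearly to $S\times S$
(default 473) and normalised per channel to mean 0.5 / sd 0.5 — training
is from scratch, so the normalisation constants are a free fixed choice,
not dataset statistics. Masks are resized with nearest-neighbour sampling,
which can never invent labels. Training augmentation: horizontal and
vertical flips with probability 0.5 each and rotation uniform in ±30°
(range unspecified in the protocol; ±30° keeps lesions in frame), with
bilinear resampling and reflection padding for the image and
nearest-neighbour for the mask; augmentation never touches validation or
test data. The 1:1:8 test:val:train ratio is implemented as the
conventional 80/10/10 split with a seeded shuffle and largest-remainder
rounding (1008 records split 806/101/101); the ratio is configurable.

## Synthetic data

The generator emulates the three regimes of the target imagery without
any clinical data: lesions are unions of 1–3 randomly placed, randomly
oriented ellipses whose outline radius is modulated by a low-order Fourier
series (total amplitude ≤ 0.3 of the radius), giving irregular but simply
connected blobs; images are a flat background (intensity 90) plus smooth
texture (blurred white noise, sd 3), plus `contrast` on the lesion
(optionally edge-blurred), plus per-pixel Gaussian noise, clipped to
0–255. Presets:

* **easy** — contrast 60 = 5x the noise sd 12, hard boundary, lesions
  5–15% of the image. A midpoint intensity threshold reaches foreground
  IoU ≈ 0.93 on this preset (tested ≥ 0.90), the sanity floor a trained
  model must approach.
* **small-target** — total lesion area 0.1–1% of the image, enforced
  < 1% per mask.
* **fuzzy-boundary** — edge blur sigma 2.5 px (≥ 2 px).

Generation is fully determined by the seed (byte-identical PNGs). What the
generator does *not* emulate: anatomical context, modality-specific
artefacts (hair, specular highlights, streak artefacts), multi-scale
texture, and inter-observer label noise — so passing the synthetic
acceptance runs demonstrates that the pipeline and optimiser work, not
clinical-grade accuracy.

## Training engine

Seeded SGD with momentum 0.9, weight decay $10^{-4}$ on convolution
weights, and polynomial decay $lr\,(1-t/T)^{0.9}$ — the standard recipe
for this network family, with defaults of 150 epochs at batch 8 and base
learning rate $10^{-2}$ for full-scale runs. The model with the best
validation mIoU is retained. All randomness (initialisation, shuffling,
augmentation, dropout) derives from the run seed; two runs with the same
seed produce identical losses.

The forward/backward engine exists twice by design: a double-precision
reverse-mode tape over RcppArmadillo kernels (the reference
implementation, used by the exported per-module functions and the gradient
tests) and a compiled single-precision executor that runs the whole
training step — forward, loss, backward, SGD update — in one call.
Single-precision training is the field's standard practice; the two
implementations agree to ~$10^{-4}$ on identical inputs, which is tested.
Convolution is im2col + GEMM with a fast path for 1x1 kernels (a single
GEMM over the batch); in the double path, GEMMs above 2 MFLOP run in
single precision while small test-scale tensors keep full double
precision.

**Desk-scale protocol.** The CPU study used throughout the tests trains on
the easy preset (200 images, 97x97 — stride-8 compatible since
96/8 + 1 = 13) for 15 epochs at batch 8. For this shortened schedule the
base learning rate is raised to 0.15: learning rate and schedule length
are coupled, and $10^{-2}$ is matched to the 150-epoch full-scale recipe,
reaching only ~0.5 foreground IoU within 15 epochs, while 0.15 crosses 0.8
around epoch 7 and plateaus near 0.85.
Validation foreground IoU ≥ 0.80 is reached for every tested seed in a few
minutes per run on one CPU. The ablation arms (baseline without CA and
with plain cross-entropy, `+MixedLoss`, `+Att`, both) are constructible
purely from configuration flags (`ca_enabled`, `loss = "ce"`).

## Numerical choices and degenerate inputs

* Batch-norm: eps $10^{-5}$, momentum 0.1, biased variance for
  normalisation and unbiased for the running estimate; evaluation uses
  running statistics, so eval-mode passes are bitwise deterministic.
* He fan-in initialisation for all convolutions; BN scale 1, shift 0.
* Pyramid bins larger than the deep map raise a configuration error
  (with bins up to 6 the input side must be at least 41).
* Empty masks: Dice smoothing handles them; metric macro-means skip
  classes absent from both prediction and truth and flag per-metric zero
  denominators rather than dividing by zero.
* Mean pixel accuracy is reported as the macro mean of per-class recall —
  the reading under which published per-class tables satisfy mPA = Recall
  — while the literal global pixel accuracy is reported in a separate
  column.

## Known limitations

* No pretrained backbone weights (training from scratch keeps the package
  download-free); real-data accuracy would benefit from pretraining.
* The synthetic generator's realism limits (above) mean desk-scale results
  bound pipeline correctness, not clinical performance.
* Single-class (lesion vs background) tooling is first-class; the K > 2
  path is implemented but not exercised by a generator preset.
* CPU-only by construction; no mixed-precision GPU path.
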