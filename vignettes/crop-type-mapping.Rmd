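---
title: "Crop-type mapping with an attention U-Net and point refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crop-type mapping with an attention U-Net and point refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Crop-type mapping assigns a crop class to every pixel of a satellite scene.
`cropseg` targets the single-date setting: one co-registered 4-band
(red, green, blue, near-infrared) reflectance raster at 10 m resolution,
labeled with four classes — *other* (non-farmland and uninsured parcels),
*rice*, *maize* and *soybean* — plus an ignore value (255) for pixels
without trustworthy labels. Two properties make this harder than generic
semantic segmentation: strong class imbalance (the background class holds
roughly 64% of labeled pixels, soybean under 4%), and the importance of
parcel boundaries, where long, narrow fields are easily misclassified as
their neighbours.

# The model

The network is a five-level U-Net-style encoder–decoder with three
additions: multi-stage efficient channel attention, PReLU activations, and
a second decoder branch that re-classifies the hardest pixels.

**Encoder.** Level 1 is a double convolution block — two rounds of (3×3
same convolution, batch normalisation, activation) — taking the 4 bands to
`base_width` channels (64 at full size). Each of levels 2–5 max-pools by 2
and doubles the channels, ending at `16 * base_width` channels at 1/16
resolution. The activation is PReLU, `f(x) = x` for `x > 0` and `αx`
otherwise, with a learnable per-channel slope initialised at 0.25; setting
`activation = "relu"` freezes `α = 0`.

**Channel attention.** Multispectral classes differ mostly spectrally, so
the encoder maps of levels 1–4 are re-weighted channel-wise before they are
used as skip connections: global average pooling gives one descriptor per
channel, a bias-free 1-d convolution of size 3 across the channel axis
(zero-padded at the ends) mixes each channel with its neighbours, and a
sigmoid produces weights in (0, 1) that scale the original map. Shapes are
unchanged and the operation is an elementwise contraction.

**Decoder.** Four stages of (bilinear ×2 upsampling, concatenation with
the attended skip at that resolution, double convolution) with output
channels `8, 4, 2, 1 × base_width`; a final 1×1 convolution maps the
64-channel (at default width) feature map to per-class logits at input
resolution. The published description of the decoder's channel arithmetic
("reduced to 1/4") cannot hold exactly together with channel-doubling
encoding and channel-preserving bilinear upsampling; this symmetric plan
preserves the stated 64-channel final map, which is the constraint we take
as binding.

**Point refinement.** After the channel softmax, each pixel's difficulty is
the margin between its top-1 and top-2 class probabilities (computed on
probabilities, not logits, so it is scale-invariant). The `k` hardest valid
pixels of each image are selected — `k = 8096` for 256×256 patches, about
12.35% of the pixels, and `round(0.1235·H·W)` for other sizes — with ties
broken by ascending flat index so runs are reproducible. For each selected
pixel, a feature vector is sampled from the level-2 encoder map (after
attention by default; a before-attention toggle mirrors the studied
variant) by bilinear interpolation at the pixel centre, concatenated with
the master branch's class probabilities at that pixel, and passed through a
shared MLP (two hidden layers of 256 by default). At inference the MLP's
argmax overrides the master label at exactly the selected pixels. During
training, masked pixels are never selected. Selection is treated as
non-differentiable: gradients flow through the sampled features and the
probability inputs, not through the margin ranking.

**Losses.** The master branch optimises `α·CE + β·Dice`. Cross-entropy is
the mean negative log-probability of the true class over non-ignored
pixels. The Dice loss is the standard multi-class soft form, one minus the
macro-average over classes of `(2·Σ x·y + ε) / (Σ x + Σ y + ε)` with sums
over valid pixels and `ε = 1e-6` smoothing; averaging per class first is
what gives minority classes equal weight, the motivation for using it under
imbalance. The default is `α = 0, β = 1` (Dice only), the best ratio in
the reference loss sweep; weights are plain multipliers so integer ratios
like 1:10 are expressed directly. The refinement branch uses its own
cross-entropy over the selected points, weighted by `cp_weight = 1` in the
total (no combination weight is published; equal weighting is the neutral
choice). If every selected point is ignored, the branch contributes 0 with
a warning rather than failing. Published loss formulas print the
cross-entropy without its negative sign and a non-standard Dice
denominator; the conventional forms are implemented.

# Data preparation protocol

A labeled scene becomes training data in four steps, all 0-based and
half-open in coordinates:

1. **Masking** — rectangles (e.g. areas without insurance labels) set
   pixels invalid; invalid pixels carry 255 in label maps and are excluded
   from every loss and metric.
2. **Tiling** — a sliding window of size 256 and stride 256 (so splits
   cannot share pixels); partial edge tiles are *dropped*, not padded,
   since padding would inject fabricated class pixels and the reference
   patch arithmetic (5505×4280 → 21·16 = 336 tiles) only works with full
   tiles.
3. **Filtering** — patches whose masked fraction is strictly above 15% are
   discarded; exactly 15% is kept.
4. **Splitting** — a seeded uniform shuffle at 8:1:1 with
   `n_val = n_test = floor(n/10)` and the remainder to train; this floor
   convention is the only one reproducing the published 143/17/17 from 177
   patches. "10-fold cross-validation" here means ten repeated seeded
   random 8:1:1 splits (seed `base_seed + fold`), not disjoint folds —
   that is what the protocol describes, and the two differ.

Reflectances pass through unnormalised by default; optional per-band
z-scores are computed on the training split only (`band_stats()`), so no
statistics leak from held-out pixels. Rasters travel as plain TIFF (float32
image, 8-bit labels) with patch origins recorded in a manifest CSV for
georeferenced stitching.

# Training

Adam at learning rate 3e-4, batch size 16, up to 150 epochs, early
stopping after 20 epochs without strict improvement of the monitored
validation metric — validation overall accuracy by default ("model
performance" is not further specified; OA is the protocol's main
indicator, and `monitor = "val_loss"` is available). The weights of the
best monitored epoch are restored on stop; restoring rather than keeping
the last weights is the choice that makes early stopping a no-regret
operation. Weight initialisation is Kaiming fan-in for convolutions,
unit/zero for batch-norm, 0.25 for PReLU slopes; no pretraining. Model
initialisation and data-loader shuffling use separate seeded streams, and
two runs with identical seeds are bit-identical.

# Evaluation

All metrics derive from a confusion matrix over non-ignored pixels:
overall accuracy (OA), average accuracy (AA, mean per-class recall — the
"average accuracy of various categories" reading), and mIoU. Classes with
no truth support in a fold are dropped from the AA mean, and classes
absent from both truth and prediction from the mIoU mean, avoiding 0/0.
Cross-validation reports the mean ± SD over folds of each fold's pooled
test-set metrics.

# The synthetic scene generator

The labeled imagery behind the published results is private insurance
data, so the package ships a generator that reproduces the *statistical
structure* the method assumes, making every stage testable end-to-end:

- **Parcels** — a Voronoi tessellation of uniformly seeded points
  (irregular convex fields, including narrow slivers — the geometry the
  point branch targets), each parcel's class drawn from the published
  pixel-share imbalance (64.2 / 19.9 / 12.0 / 3.9%).
- **Gaps** — pixels within `gap_width` (default 2) of a parcel boundary
  become background, emulating roads and field margins.
- **Spectra** — per-class 4-band mean reflectances with pairwise
  separations of roughly 1–3 noise SDs (separable but overlapping, as
  inter-class spectral similarity demands), modulated by a smooth random
  quadratic illumination surface (±5%), plus i.i.d. Gaussian noise
  (SD 0.04), clamped to [0, 1].
- **Masks** — `mask_rects` random rectangles (default 2) spanning 5–20% of
  each dimension, so the masked-fraction filter has work to do.

Defaults (512×512, 150 parcels, seed-deterministic) were fixed once from
these considerations. What the generator does **not** emulate: real
spectral texture within fields, spatial noise correlation, sensor
artefacts, mixed pixels at 10 m resolution, or temporal variation. Tests
passing on synthetic scenes therefore demonstrate that the implementation
learns and evaluates correctly under the stated assumptions — not that the
published accuracies transfer, which additionally depend on the private
dataset and GPU-scale training.

# Desk-scale problem sizes

The package's own demonstrations run on one CPU, so they scale the study
down while keeping every mechanism active: a 512×512 default scene tiled
into 64×64 patches (~60 retained), a width-16 model (`base_width = 16`),
and a 30-epoch budget trained to completion (with only ~4 batches per
epoch the validation metric is noisy early on, so the demonstrations do
not early-stop inside that budget). Under these conditions held-out OA
reaches the low-to-mid 90s, and an 8-patch run (batch 2, learning rate
1e-3, CE+Dice) memorises its training set past 99% OA — the overfit
sanity check that the optimiser and losses leave no systematic residual.
The full-size width-64 architecture is exercised structurally (shape and
parameter-census tests) rather than trained.

# Numerical choices

- Bilinear sampling uses the half-pixel-centre convention (corners not
  aligned) everywhere — decoder upsampling and point-feature sampling —
  so the sampled-feature oracle (upsample-then-gather) is exact.
- Top-k ties break by ascending flat (column-major) index.
- Softmax subtracts the per-pixel maximum; log arguments are floored at
  1e-12.
- Batch-norm uses batch statistics in training and running statistics
  (momentum 0.1) at inference; variance is floored at 0.
- `cp_k` is clamped to the number of valid pixels of each image.
- Degenerate inputs fail loudly: spatial sizes not divisible by 16, empty
  valid sets, all-ignored loss inputs and empty confusion matrices are
  errors, not silent defaults.

# Known limitations

- The forward/backward passes are hand-written dense linear algebra; they
  are exact but not GPU-accelerated, so full-size 256×256 training is out
  of desk reach — by design, the full architecture is validated
  structurally.
- Only the channel-attention variant studied here is built in; the
  attention module is a single pluggable site (`eca = FALSE` disables it)
  but alternative modules are not implemented.
- No augmentation, learning-rate schedule or weight decay (none are part
  of the protocol), and no multi-temporal support.
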