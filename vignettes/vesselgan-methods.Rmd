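---
title: "Adversarial dual U-Net vessel segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial dual U-Net vessel segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselgan)
```

## The problem

Time-of-flight MR angiography (TOF-MRA) renders flowing blood bright without
contrast agents, and segmenting the vessel tree from such volumes underpins
surgical planning and cerebrovascular diagnosis. Manual slice-by-slice
annotation is slow and expert-bound, while the labelled datasets available
for training are tiny — often a handful of volumes — and the classes are
severely imbalanced: vessel pixels are a few percent of each slice.
`vesselgan` implements a conditional generative adversarial approach built
for exactly this regime: an image-to-image generator that maps a grayscale
slice to its segmentation map, trained against a patch-level discriminator
plus a heavily weighted L1 reconstruction term.

## Model

**Generator.** Two U-Net-shaped subnets applied in sequence. Subnet 1 is a
classic U-Net: at each of 4 levels a stride-2 3×3 convolution halves
resolution and doubles channels, followed by a refining 3×3 convolution,
each with instance normalization and LeakyReLU (slope 0.2); the decoder
mirrors this with stride-2 3×3 transposed convolutions and concatenation
skip connections from the matching encoder level. Subnet 2 has the same
topology but every refining convolution is replaced by a residual block
`y = LeakyReLU(F(x) + x)` with
`F(x) = IN(conv(LeakyReLU(IN(conv(x)))))`, and its skip connections are
merged by addition rather than concatenation. The additive merge is a
deliberate design choice: a residual block requires its input and output
channel counts to agree, which a concatenation would break, and it keeps the
two subnets close to the same size — consistent with the architecture being
roughly "two U-Nets" in parameter budget. The link between the subnets is
the 1-channel tanh output of subnet 1; there are no cross-subnet skips.
Dropout (p = 0.1) at both bottlenecks plays the role of the GAN noise input
`z`. The final layer is a 1-channel 3×3 convolution with tanh, so outputs
live in (−1, 1) and masks are recovered by thresholding at 0.

**Discriminator.** A PatchGAN: four stride-2 4×4 convolutions (instance
norm + LeakyReLU), dropout (p = 0.1), and a final single-filter same-padded
4×4 convolution with sigmoid. A 256×256 input yields a 16×16 map, each cell
scoring one receptive-field patch as real or fake. The discriminator is
conditional: it receives the input slice concatenated channel-wise with a
real or generated mask.

**Channel widths.** The per-level widths follow a classic doubling ladder
from a base width. The defaults (generator 119, discriminator 101) were
calibrated once, analytically from the parameter-count formula, so the
default models carry ≈65 million and ≈6.9 million trainable parameters —
the documented scale of this architecture class at 256×256. Both counts are
verified by the test suite and recomputed by `scripts/acceptance.R`.

**Objectives.** The generator minimises
`BCE(D(x, G(x,z)), 1) + λ · mean|y − G(x,z)|` with λ = 75: the 75-to-1
weighting toward L1 is what stabilises training under extreme class
imbalance, while the adversarial term sharpens thin structures. The
discriminator minimises
`0.5 · ½ [BCE(D(x,y), 1) + BCE(D(x,G(x,z)), 0)]`; the leading 0.5 halves
its optimization pace relative to the generator ("pace factor"),
implemented as a multiplier on its objective, not as a halved learning
rate. Probabilities are epsilon-clamped at 1e−7 before logs; in the
training loop the gradient is taken through the logits directly, which is
algebraically identical and numerically stable.

**Optimization.** Generator: Adam, learning rate 2e−4, β₁ = 0.9,
β₂ = 0.999. Discriminator: RMSProp at the same rate with decay 0.9 and
momentum 0.9. An optional per-epoch exponential learning-rate schedule
(factor 0.96, enabled by default) decays both. Each step updates the
discriminator once (generator frozen) and then the generator once
(discriminator frozen); the freeze contracts are asserted by weight
snapshots in the tests. Epoch count is not fixed by the method; the default
is 100 with an optional early stop after 10 epochs without validation-Dice
improvement.

## Preprocessing and augmentation

Raw slices are cleaned by ROI masking: pixels at or above an intensity
threshold (default 10 on the 0–255 scale; boundary pixels exactly at the
threshold are kept) define a binary mask that is repaired by a
morphological closure (9×9 square structuring element by default — the
simplest reading of a bare "kernel size 9"; a disc is available). The mask
multiplies the slice, slices are resized to the network resolution (256×256
by default; bilinear for images, nearest-neighbour for masks so they stay
binary), and intensities are affinely mapped to [−1, 1] to match the tanh
output. The closure follows the standard morphology border convention
(outside counts as background for dilation and as foreground for erosion);
this is the convention under which a uniformly bright slice closes to an
all-ones mask. The ROI mask is computed at native resolution before
resizing. CLAHE (clip limit and tile grid configurable, defaults 2 and 8×8)
is available for low-contrast modalities such as two-photon microscopy; a
1×1-tile configuration is computed exactly as global histogram
equalization, its mathematical limit.

Augmentation doubles as regularisation for few-volume training: a
left–right mirror flip (anatomically plausible given lateral brain
symmetry) and a random patch zoom that crops a window at a uniform random
origin with zoom factor drawn from (1, 2] and rescales it to full size.
Both are always applied jointly to slice and mask; the default expansion is
two augmented copies per slice (one flip, one zoom). Augmentation is
applied on the fly to training folds only — the volume-level split happens
before any expansion, so no augmented sample can leak into validation.

## Synthetic phantoms

The real volumes this method targets are private clinical data, so the
package ships a phantom generator that reproduces the properties that
matter for the pipeline: bright, mildly tortuous tubular structures of
1.5–3 px radius over a darker noisy background, with exact ground-truth
masks and a vessel fraction of a few percent. Centerlines are smoothed 3D
random walks (per-step angular perturbation scaled by a tortuosity
parameter, reflected at volume boundaries and biased toward the slice
plane) so adjacent slices share structure the way a real angiographic stack
does; tubes are rasterised by thresholding the exact 3D distance to the
centerline, which makes the mask analytic rather than approximate; the
background is clipped additive Gaussian noise, the simplest stand-in for MR
background noise. A validity constraint enforces learnable contrast: the
vessel intensity floor must exceed the background mean by at least two
noise standard deviations.

What the phantoms do *not* emulate: Circle-of-Willis anatomy, flow-related
intensity variation, bias fields, partial-volume effects, or skull/tissue
background structure. Passing the phantom-based training checks therefore
demonstrates that the architecture, losses, optimizers and evaluation
machinery work end to end and can learn tubular bright-on-dark structure
from few volumes — not that clinical-grade Dice scores transfer to real
MRA.

## Evaluation protocol

Metrics are computed from confusion counts pooled over all pixels of a
validation volume (not averaged per slice): Dice `2TP/(2TP+FP+FN)`,
precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, specificity
`TN/(TN+FP)`. Ratios with empty denominators are reported as `NA`, never
silently as 0, so they cannot corrupt averages. An independent set-formula
Dice (`2|A∩B|/(|A|+|B|)`) is kept as a permanent cross-check and must agree
exactly. Error maps are the absolute difference between truth and
prediction; their positive count equals FP + FN by construction. k-fold
cross-validation (k = 4 by default) assigns volume *i* to fold
`((i−1) mod k)+1`, trains one model per fold on the out-of-fold volumes
under identical hyperparameters, and reports per-fold rows plus an
unweighted average row. Metrics are computed at model resolution (256×256),
not after upsampling back to native resolution.

## Numerical choices and problem sizes

All layers are implemented in the package (im2col/col2im in C++, matrix
products through BLAS) with backward passes verified against central finite
differences of their own forward passes, both per layer and through the
assembled networks. TensorFlow-style "same" padding is used throughout
(extra padding pixel at bottom/right when the total is odd). Instance
normalization uses ε = 1e−5 and population variance. Weight initialisation
is He-normal by receptive-field fan-in; instance-norm scales start at 1,
shifts at 0. All randomness — phantom geometry, weight init, shuffling,
augmentation draws, dropout — flows from explicit integer seeds, so runs
are bit-reproducible.

Tests and the worked examples run at desk scale on one CPU: 64×64×32
phantom volumes, base width 8, batch 10, ten epochs — small enough to
train in minutes while exercising every component at full depth. The
default configuration (256×256, base widths 119/101) is the full-size
model; it is built and measured, but not trained, in the automated checks.

## Known limitations

- 2D: slices are segmented independently; no 3D convolutions or
  inter-slice context beyond what the phantom generator encodes.
- The adversarial game inherits GAN training sensitivity; the heavy L1
  weighting masks most of it at phantom scale, but real-data training may
  need the early-stop and schedule options.
- No pretrained weights, attention gates, or deep supervision.
- CLAHE tile counts must be ≥ 2 per side for the tiled path (the 1×1 case
  is served by exact global equalization).
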