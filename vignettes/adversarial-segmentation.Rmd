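---
title: "Conditional adversarial 3D segmentation with multi-axis attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional adversarial 3D segmentation with multi-axis attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Liver and liver-tumor delineation in abdominal CT is a voxel-wise
classification task with two structural difficulties: extreme class
imbalance (a tumor can occupy a vanishing fraction of a `D x 512 x 512`
scan) and strong three-dimensional context (a liver boundary is ambiguous
on a single axial slice but obvious across planes). `cganseg` implements a
segmentation model that addresses both: a U-shaped volumetric generator
whose skip connections are gated by a *multi-axis attention* (MA)
mechanism, trained adversarially against a conditional discriminator with
a Tversky overlap loss.

Everything — networks, backpropagation, the AdamW optimizer, the training
loop — is implemented natively in R on top of exact im2col + BLAS
convolutions written in C++. This keeps the package free of deep-learning
framework dependencies and makes every gradient auditable: the test suite
checks each layer against finite differences.

# The model

## Generator

The generator is an encoder-decoder with four 2x downsamplings (max
pooling) and channel schedule $b, 2b, 4b, 8b, 16b$; at the default
$b = 16$ a `1 x D x 256 x 256` input reaches a bottleneck of shape
`256 x D/16 x 16 x 16`. All convolutions are 3x3(x3) with batch
normalization and ReLU; decoding upsamples by trilinear-style linear
interpolation so each decoder stage matches its encoder counterpart's
pre-pooling shape, and the two are concatenated through the skip
connections. A 1x1x1 convolution plus sigmoid produces a per-voxel
foreground probability. Spatial input dimensions must be divisible by 16;
`pad_depth()` reflect-pads the depth axis and records the original depth
so predictions can be un-padded.

The pipeline trains one binary model per target: liver (labels 1 and 2
merged) and tumor (label 2), each with the single-channel sigmoid head,
binarized at 0.5 at inference. Joint multi-class output is deliberately
out of scope; the composition of the two binary models into a 3-class map
happens in post-processing.

## Multi-axis attention

Each skip connection passes the encoder features through an MA block
before concatenation. The block runs three *slice feature projection*
(FP) branches, one per anatomical plane. An FP branch:

1. pools the `C x D x H x W` features along the plane's normal axis with
   both max and mean and sums them, giving the shared key/query
   `K = Q = Max(x) + Mean(x)` (shape `C x H x W` for the axial branch,
   `C x D x H` sagittal, `C x D x W` coronal);
2. refines `K` with two 3x3 2D convolutions, concatenates with `Q`, and
   fuses with two 1x1 convolutions (`2C -> C` then `C -> C`);
3. replicates the fused 2D map along the reduced axis into an attention
   matrix `R` of the input shape, multiplies it with a value tensor
   `V = conv1x1x1(x)`, stacks the product with the input, and reduces the
   stacked pair by summation followed by a spatial mean — a per-channel
   gate of shape `C x 1 x 1 x 1`.

The three gates are fused with learnable weights $\beta$ constrained to
the probability simplex, and applied multiplicatively:
$y = \sum_{\alpha=1}^{3} \beta_\alpha \cdot \mathrm{FP}^{(\alpha)}(x) \cdot x,
\qquad \sum_\alpha \beta_\alpha = 1.$

Design choices where the construction was genuinely open:

* **Simplex constraint.** $\sum\beta = 1$ is enforced by a softmax over
  three unconstrained logits, so the constraint holds exactly after every
  optimizer update rather than being renormalized periodically.
* **Final reduction.** The stacked pair `(R * V, x)` has shape
  `C x 2 x D x H x W`; producing a `C x 1 x 1 x 1` gate requires reducing
  both the pair dimension and all of space. We sum over the pair and
  average over `D, H, W` — the only reduction order consistent with the
  stated output shape; the mechanism's written description admits other
  readings, so this one is documented rather than asserted.
* **Replication axis.** The 2D attention map is replicated along each
  branch's own reduced axis (depth for axial, width for sagittal, height
  for coronal).
* **No activations inside FP.** The 3x3 and 1x1 convolutions in the FP
  branch carry no normalization or nonlinearity; nothing in the
  construction requires one, and the zero-parameter limit then has a
  closed form (the gate reduces to the per-channel spatial mean of `x`)
  which the tests exploit as an exact oracle.

## Discriminator and adversarial training

The discriminator receives the CT concatenated with a real or generated
label map and applies three stride-2 3x3x3 convolutions (widths 32, 64,
128), each followed by ReLU and dropout 0.5, then global average pooling,
a fully connected layer and a sigmoid score. Dropout keeps the
discriminator from overpowering the generator; global pooling makes it
input-size agnostic.

Training alternates one generator update and one discriminator update per
batch. During the generator step the discriminator's parameters are
frozen (asserted bit-identical in the tests); during the discriminator
step the generator only samples fake labels, with no gradient flowing
back. Two adversarial losses are provided:

* `"nolog"` (default): the log-free form — the discriminator minimizes
  `-mean(D_real) + mean(D_fake)`, the generator `-mean(D_fake)`. No
  gradient penalty or weight clipping is added.
* `"bce"`: ones/zeros binary cross-entropy.

The generator's total loss adds the Tversky loss with weight
$\lambda = 1$:
$T(y, g) = \frac{\sum_i y_i g_i}{\sum_i y_i g_i + \alpha \sum_i (1-y_i) g_i + \beta \sum_i y_i (1 - g_i)},
\qquad \mathrm{loss} = 1 - T.$
$\alpha$ weights false positives and $\beta$ false negatives; the
defaults $\alpha = 0.7, \beta = 0.3$ trade precision for recall, which
matters when missing a lesion is costlier than a false alarm. At
$\alpha = \beta = 0.5$ the index reduces exactly to soft Dice (a tested
identity). A smoothing constant of $10^{-6}$ in numerator and denominator
guards the empty-foreground case. The index as defined is a similarity
(1 = perfect); the quantity minimized and logged is `1 - index`, which is
the form whose training curves decrease toward zero.

## Optimization schedule

AdamW (decoupled weight decay $10^{-2}$ — the optimizer family's default;
only the optimizer name and learning rate are externally specified) with
initial learning rate `2e-4` and batch size 2. After each epoch the mean
validation Dice of the trained target(s) is computed on raw binarized
predictions (post-processing is reserved for final evaluation); if it
fails to improve by at least `1e-5` for 30 consecutive epochs the
learning rate is halved, and training stops after 60 stale epochs or 300
epochs. The `1e-5` margin exists so float jitter cannot reset the
patience counters. The best-validation parameter state is checkpointed
and restored at the end; reloading a checkpoint reproduces the recorded
validation metric exactly.

Variable-depth volumes are handled by training on random depth crops
(`crop_depth`, default 32 slices, divisible by 16) so two cases fit a
batch, while validation and inference run on whole, reflect-padded
volumes.

## Normalization at batch size 2

With batch size 2 processed sample-by-sample, batch-normalization
statistics are per-volume — instance normalization in practice. The
layers track running moments, but inference also uses per-volume
statistics by default (`use_running = FALSE`): on the tiny overfit runs
used for testing, running averages would lag the per-call statistics and
make evaluation-mode predictions diverge from training behaviour for no
benefit. This is a deliberate, documented departure from
running-statistics evaluation; it matters only when a trained model is
applied to data whose intensity distribution differs strongly from
training, which the windowed, fixed-scale inputs here preclude.

## Head initialization

The final 1x1x1 convolution is initialized at zero, so the untrained
generator outputs probability exactly 0.5 at every voxel. With a
randomly initialized head, global overlap losses of the Tversky family
admit a spurious basin: when the head happens to start all-negative,
every voxel sits below the 0.5 decision threshold and the soft loss can
keep improving the *ordering* of probabilities indefinitely while the
binarized prediction stays empty (we observed exactly this on some
initialization seeds — a steadily decreasing Tversky trace with a
hard Dice pinned at zero). Starting at the symmetric point removes the
basin: the first gradient step sets each voxel's polarity. The only cost
is that no gradient reaches layers below the head until the head's first
update, which is irrelevant after one optimizer step.

# Preprocessing and post-processing

CT preparation follows two steps. *Labeled-slice cropping* finds the
first and last depth slice with any nonzero annotation and drops
everything outside. *Windowing* clips intensities to the soft-tissue
analysis range `[-30, 170]` HU. (A window is conventionally quoted as a
level/width pair; the operational statement used throughout this package
is the clipping range itself, which corresponds to level 70 with a width
of 200.) Windowed volumes are then mapped linearly to `[0, 1]` over the
fixed window — not per volume, so intensities remain comparable across
cases — and optionally resized in-plane (bilinear for images, nearest
neighbor for labels).

Predicted liver masks are cleaned by connected-component analysis: with
`x` the voxel count of the largest component, components with count
strictly below `rate * x` are removed (default rate 0.3; ties survive
exactly as the strict inequality dictates). There is only one liver, so
satellite components are anatomically implausible. Components are
labelled by building the voxel adjacency graph (26-connectivity by
default; 6 and 18 are available since component counts depend on it) and
taking its connected components via igraph. Tumor predictions are
intersected with the surviving liver at composition time; the liver
channel itself is never altered.

# Evaluation metrics

Dice `2|S∩G|/(|S|+|G|)`, Jaccard `|S∩G|/|S∪G|`, HD95 and ASD. Surface
distances operate on boundary voxels (foreground voxels with a background
face-neighbor). HD95 is the maximum of the two directed 95th-percentile
surface distances; ASD the mean of the two directed mean distances.
Numerical conventions that published implementations differ on, fixed
here and config-visible:

* percentiles interpolate linearly between order statistics (R type 7);
* distances are in millimeters when spacing metadata exists, else voxels;
* both masks empty: dice = jaccard = 1, hd95 = asd = 0 (a perfectly
  predicted absent structure); exactly one empty: dice = jaccard = 0 and
  distances return a sentinel (`NA` by default).

All four metrics are verified against independent all-pairs brute-force
oracles on random small masks to 1e-9.

# The synthetic phantom

`make_phantom()` emulates the statistical structure of annotated
abdominal CT at desk scale: an elliptical soft-tissue "body" (mean -80
HU) against air at -1000 HU, a liver ellipsoid (60 ± 10 HU) inside it,
and 0-3 hypodense spherical tumors (25 ± 10 HU) rejection-sampled to lie
entirely within the liver (placement uses the liver ellipsoid shrunk by
the tumor radius; 100 failed attempts raise an error). Per-region
intensities are drawn per voxel, blurred with a 1-voxel Gaussian to mimic
partial-volume boundary softening, and additive noise (sd 5 HU) is
applied. The default grid is `32 x 64 x 64` with depth divisible by 16.
The phantom is a pure function of its config including the seed.

What the phantom does *not* emulate: neighboring organs of similar
intensity, contrast phases, breathing or reconstruction artifacts,
irregular tumor shapes, and anisotropic spacing. Tests passing on
phantoms therefore demonstrate that the machinery — losses, gradients,
alternating optimization, metrics, post-processing — is correct and that
the model class can fit CT-like structure; they say nothing about
segmentation accuracy on real scans.

# Test-scale choices

The suite exercises everything at sizes a single CPU handles in minutes:
unit tests run networks with `base_channels = 2` on `16 x 32 x 32`
crops; the end-to-end convergence check overfits the full adversarial
model (`base_channels = 4`, multi-axis attention on, no-log adversarial
loss plus Tversky) on two `32 x 64 x 64` phantoms within 300 alternating
steps. That overfit run uses the default optimizer and schedule (AdamW at
`2e-4`, plateau halving, early stopping); only the architecture width is
scaled down, which keeps a forward-backward pass near a second on one
CPU. The default width 16 is exercised separately through the
bottleneck-shape contract at `256 x 256`.

# Known limitations

* Single-sample batching: gradients are accumulated per sample, so
  normalization statistics are per-volume (see above) rather than joint
  across the batch.
* The no-log adversarial mode keeps the sigmoid discriminator; when the
  discriminator saturates its gradient to the generator vanishes, as
  visible in smoke-run traces where `d_loss` approaches -1 and the
  Tversky term drives the remaining progress. No Lipschitz constraint is
  applied; the adversarial objective used here includes neither.
* Surface distances are exact nearest-neighbor computations, O(|S|·|G|)
  per case with chunking; adequate for desk-scale masks, not optimized
  for 512³ clinical volumes.
* The CLI trains one class per invocation; the 3-class map is assembled
  at prediction time from the liver and tumor checkpoints.
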