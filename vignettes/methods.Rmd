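---
title: "Semi-supervised bladder wall and tumor segmentation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised bladder wall and tumor segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, what the synthetic phantoms do
and do not emulate, the numerical choices, and the design decisions taken
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The segmentation problem and the model

On T2-weighted-like images the urine-filled lumen is bright, the muscular
bladder wall is a thin dark ring around it, and wall-attached tumors have
intensities between the two, often with blurred boundaries. The package
segments four classes — background (0), urine (1), wall (2), tumor (3) —
with an encoder–decoder convolutional network in the SegNet family:

* **Encoder:** nine convolution blocks (3×3 convolution with
  size-preserving padding → batch normalization → leaky ReLU) arranged
  3-3-3 between three 2×2 max-pooling layers with stride 2. Each pooling
  stage records the per-window argmax position and the pre-pooling
  spatial size. Channel widths double per stage:
  `base_width × (1, 2, 4)`.
* **Decoder:** three index-preserving unpooling stages interleaved 1-1-2
  with four convolution blocks. Unpooling writes each retained maximum
  back at its recorded position and zeros elsewhere, so fine spatial
  detail survives the bottleneck without learned upsampling — important
  for a structure as thin as the wall.
* **Heads:** a 1×1 convolution + sigmoid for reconstruction
  (pre-training), or a 1×1 convolution + per-pixel softmax over the four
  classes for segmentation.

The leaky ReLU is `f(x) = x` for `x ≥ 0` and `a·x` otherwise, keeping
gradient flow through inactive units; `a = 0.01`.

The exact conv-block interleaving and the channel plan are not forced by
the architecture family, which fixes only the counts (nine encoder
blocks, three pools, four decoder blocks, three unpools) and the spatial
symmetry. The 3-3-3 / 1-1-2 arrangement used here preserves those counts
and keeps the output size equal to the input size for any input whose
side is divisible by `2^3 = 8`; the transfer report produced by
`transfer_weights()` lists every block so the arrangement is
machine-readable.

## Stage 1: wall-enhanced self-supervised pre-training

Patches are randomly cropped, and two masked views of each patch are made
by sampling 5–10 axis-aligned square holes with sides of 15–20 px
(per-hole), filled with i.i.d. uniform noise on [0, 1]. The network
reconstructs each view; the objective is the sum of a *contrast
consistency* term (L1 between the two reconstructions — the network must
agree with itself about content it cannot see) and a *reconstruction
observation* term (L1 of each reconstruction against the unmasked
patch). Optimizer: Adam.

Open choices, and what the package does:

* *Hole geometry.* "Size" is read as the side length in pixels of a
  square hole — the simplest shape consistent with a scalar size. Holes
  may overlap; overlaps simply overwrite.
* *Noise inside holes.* Uniform on [0, 1] by default (maximal corruption
  entropy, range-valid); a clipped-Gaussian option exists
  (`mask$noise: gaussian`).
* *Reduction.* The pixel sums of the written losses are implemented as
  means over pixels so the loss scale — and therefore meaningful learning
  rates — does not change with patch size; `reduction = "sum"` restores
  the literal sums.

## Stage 2: semi-supervised segmentation

The segmentation network inherits every trunk parameter (and batch-norm
statistics) from stage 1; the softmax head and the VAE branch start
random. Training batches mix labeled and unlabeled samples half and half
(keeping both loss terms populated every step; unlabeled samples are
drawn with replacement when the pool is exhausted).

One epoch covers the full semi-supervised pool — the larger of the
labeled-training and unlabeled sets — with the smaller pool recycled, so
unlabeled data is fully traversed even when labels are scarce.

**Dice-focal loss** (labeled samples only). The focal term
`−α_t (1−P_t)^γ log P_t`, averaged over pixels, concentrates gradient on
hard pixels: per-class weights are urine 0.1, wall 0.6, tumor 0.8, with
background set to 0.1 (equal to urine — both are large easy classes; the
weight is configurable). `γ = 2`, the standard focal default. The Dice
term is the soft per-class loss `1 − (2|x∩y|+e)/(|x|+|y|+e)` with
probability-weighted intersection, averaged over the foreground classes
present in the ground truth (background excluded, matching where the
focal weights are specified; configurable). It is 0 on a perfect match
and tends to 1 on total mismatch as `e → 0`. Probabilities are clamped at
`1e−7` inside logs; the Dice smoothing default is `e = 1e−6`.

**Variational loss** (all samples). The bottleneck feature field is
global-average-pooled and mapped by two affine layers to the posterior
parameters `(μ1, log σ1²)` of a diagonal Gaussian (latent dimension 16 by
default). A reparameterized sample is affine-mapped back to channel
space, broadcast over the bottleneck's spatial grid, and decoded by two
conv blocks into a reconstruction of the bottleneck features. The loss is
the reconstruction MSE plus the closed-form KL divergence against the
standard normal, `½ Σ (μ² + σ² − log σ² − 1)`. Unlabeled images
contribute gradient through this branch only — that is the semi-supervised
mechanism. Two deliberate choices:

* *Reconstruction target.* The branch reconstructs the encoder's last
  feature field rather than the input image (the textual reading; the
  alternative reading of the loss notation would target the image). The
  feature target keeps the branch small and size-agnostic.
* *Stop-gradient on the target.* The MSE target is treated as a constant;
  otherwise the encoder could trivially shrink its features to minimize
  the loss.
* *Broadcast decoder.* The latent is mapped to a channel vector and
  broadcast spatially instead of an affine map to a fixed `C×h×w` tensor,
  so one parameterization serves every input size.

**Adaptive learning rate.** With `n` annotated training samples, the
ratio `β = LR2/LR1` between the learning rate of randomly initialized
layers and that of pre-trained layers follows the anchor table
(42, 0.02), (21, 0.2), (12, 2), (4, 10), (1, 20). Between anchors the
package interpolates log-linearly in `(log n, log β)` — the smoothest
monotone fit to a ratio spanning three orders of magnitude over a
42-fold range of `n` — and clamps to the nearest endpoint outside
[1, 42]. Optimizer: AdamW (decoupled weight decay 0.01 on convolution and
affine weights only). Model selection: mean foreground Dice on a held-out
validation fraction (default 20%) of the labeled data.

## Stage 3: inference

**Test-time augmentation.** The weak augmentation set is restricted to
transforms that are exactly invertible on the pixel grid — horizontal and
vertical flips and rotations by 90°/180°/270° — because label and
probability fields must return to the original image space without
interpolation; `register_tta_transform()` enforces exact inversion at
registration. Merging averages the inverse-transformed probability maps
before the argmax (majority voting is available via `merge = "vote"`);
probability averaging uses the full calibration of the maps where voting
discards it, and makes merging permutation-invariant.

**Segmentation correction.** The anatomical prior is one bladder per
image whose urine/wall/tumor union is connected and hole-free. Correction
keeps the largest foreground connected component (8-connectivity;
size ties go to the first component in row-major order), then fills
interior holes (background regions not 4-connected to the image border).
The 8/4 connectivity pairing is the standard duality that avoids
checkerboard paradoxes; both are configurable. Filled pixels take the
majority class of their 8-neighborhood foreground ring, iterated inward —
holes occur inside urine or tumor and should inherit the surrounding
tissue. Component filtering runs before hole filling; the correction is
idempotent, and argmax ties break toward the lower class index.

## The phantom generator

The clinical images behind the method are not publicly available, so the
package generates synthetic bladder phantoms with the statistical
structure the method assumes: one bladder per image; a random-ellipse
lumen; a topologically closed wall ring of random thickness made by
dilating the lumen ellipse; with probability 0.9 a tumor — a perturbed
disk grown from a random wall pixel, replacing the wall/lumen pixels it
covers; Gaussian boundary blur; additive clipped Gaussian noise.
Intensity means are urine 0.85 > tumor 0.45 > wall 0.25 > background
0.10, making wall/tumor discrimination nontrivial (their intensities
bracket the blurred boundary) yet learnable at desk scale.

Defaults (image size 96; lumen semi-axes 0.18–0.30 of the image; wall
4–7 px; tumor radius 6–12 px; blur σ = 1 px; noise σ = 0.04) were chosen
once as a realistic desk-scale miniature of the imaging setting and are
not tuned per experiment.

What the phantoms do **not** emulate: MRI physics (bias fields, partial
volume, coil inhomogeneity), anatomical variability beyond ellipses and
blobs, multi-focal tumors, 3D continuity across slices, and annotation
noise. Passing the phantom study therefore shows that the pipeline's
machinery — pre-training transfer, semi-supervised objective, adaptive
rates, TTA, correction — works end to end under the assumed image
structure; it does not certify clinical performance.

## Scale, defaults, and numerical choices

The full-scale clinical configuration (512×512 slices cropped to
256×256, batch 16, 100 epochs, learning rate 1e−4) targets GPU training
on a clinical cohort — roughly 26k optimizer steps. The package's
defaults are a CPU-scale miniature: 96×96 phantoms, batch 8, 20
pre-training and 40 segmentation epochs, base width 8 (channel plan
8-16-32; the VGG16-scale widths typical of this architecture family are far
heavier than this task needs). At this scale the run makes ~500 optimizer
steps; since Adam's parameter displacement scales with
`lr × steps`, the desk-scale configuration uses `lr = 1e−3` so that total
displacement is comparable to the clinical-scale regime. The β ratio policy is
applied exactly as tabulated. All of these are plain configuration values
(`default_config()`), so the clinical-scale values can be restored verbatim
for full-scale runs.

Other numerical choices: batch-norm ε `1e−5`, momentum 0.1 on running
statistics (evaluation uses running statistics; the variational sample is
replaced by the posterior mean at inference, making prediction
deterministic); He initialization for convolutions; pooling ties take the
first maximal element in row-major window order, making
unpooling reproducible; Adam/AdamW with β₁ = 0.9, β₂ = 0.999, ε = 1e−8.
Training is deterministic given the configuration seed (a fixed seed is
derived for every crop, mask, batch shuffle and latent draw).

Degenerate inputs: a wall thicker than the minimum lumen radius is
rejected at configuration time; crops larger than the image, holes larger
than the patch, odd spatial sizes at a pooling stage, and shape
mismatches in losses or weight transfer are errors naming the offending
quantity; an all-background map passes through correction unchanged with
a warning; empty masks yield Dice 1 when both are empty (correct absence
is not penalized) and an error for the Hausdorff distance (undefined).
Classes absent from a case's ground truth are excluded from that class's
averages in `evaluate()`.

The low-label ablation in the acceptance suite (3 labeled phantoms,
pre-trained vs. scratch initialization, five seed repetitions) uses a
reduced 8-epoch protocol per run — ten fine-tuning runs share one CPU
budget — and compares raw argmax predictions so the comparison isolates
the initialization rather than the post-processing.

## Known limitations

* 2D slice-wise only; no 3D context or volume synthesis.
* The phantom study bounds what the tests can show about clinical data
  (see above); clinical per-cohort accuracy figures are not reproducible
  without the private cohort.
* The full Hausdorff distance (not the 95th percentile) is reported, in
  pixel units with an optional spacing multiplier.
* One bladder per image is assumed by the correction stage; multi-focal
  or multi-structure images would need the correction disabled.
* The β anchor table is defined on n ∈ [1, 42] annotated samples; outside
  that range the policy clamps, which is an extrapolation choice, not an
  empirical one.
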