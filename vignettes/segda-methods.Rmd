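---
title: "Methods: source-relaxed domain adaptation for anisotropic 3D segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-relaxed domain adaptation for anisotropic 3D segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(segda)
```

## The problem

Surgical planning for prostate cancer needs per-patient segmentations of
the gland and of two thin critical structures — the neurovascular bundles
(NVB) and the external urethral sphincter (EUS) — on thick-slice axial
T2-weighted MRI.  A network trained at one site (the *source* domain)
degrades badly at another site whose scanner, coil and protocol differ
(the *target* domain); with an endorectal coil the very shape and
location of the periprostatic anatomy change.  Privacy rules often forbid
sharing the source images and labels, so adaptation must work from the
*source model alone* plus a handful of labeled target cases and a pool of
unlabeled ones.

`segda` implements this source-relaxed, semi-supervised domain
adaptation pipeline end to end, together with a synthetic anisotropic
phantom generator so every stage can be exercised and validated on one
CPU without any clinical data.

## The segmentation network

The supervised backbone is an anisotropic 3D U-Net over `C = 4` classes
(background, gland-like blob, EUS-like axial tube, NVB-like paired
tubes).  Each resolution level applies two 3×3×3 convolutions, each
followed by affine instance normalization and ReLU; the second
convolution of every non-bottom level doubles the channels, so 16
first-layer filters grow to 128 in the bottom-most level across four
levels.  Max-pooling is anisotropic — 2×2 in-plane at every transition,
with the slice axis pooled only at the deepest transition, where two
in-plane halvings have brought the effective in-plane spacing up to the
slice spacing (0.5 mm × 4 vs 3 mm for the prostate recipe).  The decoder
mirrors the encoder with parameter-free nearest-neighbour upsampling,
skip concatenation and two convolution blocks per level; a 1×1×1
convolution with softmax yields voxelwise class probabilities.

The published description of this architecture leaves the normalization
type, upsampling operator and channel progression open; the one objective
fingerprint is its trainable-parameter count.  The reconstruction above
reproduces it exactly:

```{r fingerprint}
model <- build_model(model_spec(), seed = 1)
count_parameters(model)      # 3197028
group_parameter_counts(model)
```

Several nearby variants (transposed-convolution decoders, constant
per-level channels, normalization-free blocks) were enumerated and none
matches the printed count; the in-level-doubling encoder with
parameter-free upsampling and affine normalization is the unique match in
that family.  If other reconstructions also match, the count cannot
distinguish them; this one is consistent with every stated property
("anisotropic upsampling", 16 first / 128 bottom filters, four-channel
softmax output).

`parameter_groups()` partitions the parameters into encoder, bottleneck
(the bottom-most level) and decoder.  The final classifier is assigned to
the decoder group, so stage-I transfer learning — which freezes "the
decoder" — also freezes it; this is the conservative reading and is
exposed through `train_config(trainable_groups = ...)` for users who want
the classifier trainable.

## Losses

Supervised training minimizes the negative multi-class soft Dice,
averaged over all four classes (background included — a switch
`include_background = FALSE` is provided since published loss
formulations differ on this point), with an additive smoothing
`eps = 1e-5` in the denominator only.  Keeping the numerator exact makes
the empty-class convention literal: a class with no mass inside the mask
contributes `2·0 / (0 + 0 + eps) = 0` rather than an arbitrary bonus.

Self-learning uses the *partial Dice loss*: voxels of a pseudo-label that
carry no class (because no probability exceeded the post-processing
threshold, or the label was removed by component filtering) are marked
`UNLABELED` and excluded through a binary mask `M`, and each case is
scaled by a scalar weight `w ∈ [0, 1]`.  The loss is exactly linear in
`w` and collapses to the supervised Dice loss when `M ≡ 1, w = 1`; both
identities, and the complete insensitivity of the loss to masked voxels,
are asserted in the test suite.  A voxel index collision in the printed
formula (the same index used for voxels and cases) is resolved the way
the uncertainty-weighting section implies: inner sums run over voxels,
`w` is per case, and the batch aggregates cases by unweighted mean.

## Ensembles, uncertainty and pseudo-labels

A deep ensemble of `k` members (5 at full scale, 3 in the desk-scale
benchmark) varies random initialization, mini-batch order and the
train/validation split per member.  The ensemble mean `mu` feeds both
prediction and uncertainty: the voxel entropy `H = -sum(mu_c log mu_c)`
(natural log; any base cancels under the max-normalization below, which a
property test asserts) is averaged over **all** voxels of a case — the
published reduction to a "case-based" scalar is not specified further,
and the all-voxel mean is the least informative-prior choice; it is
exposed as the `case_entropy()` building block so other reductions can be
swapped in.

Case entropies are normalized by the maximum over the *current*
pseudo-label pool (recomputed every self-learning cycle, since the pool's
uncertainty shrinks as the models adapt) and the pseudo-label weight is
`w = 1 - H/max(H)`.  Consequences worth knowing: the most uncertain case
always gets weight 0; if all entropies are equal and positive, *all*
weights are 0 (the cycle then learns from the labeled cases only); if all
are 0, weights are 1.  With a single unlabeled case the normalization
would silence the case unconditionally, so the fixed weight 0.5 is used
with a warning.  The entropy weight *replaces* the fixed 0.5 of the
non-uncertainty arms rather than multiplying it, following the wording
that the weight "is set to" `1 - H`.

Pseudo-labels are the post-processed ensemble mean: threshold at
`tau = 0.5` (the published pipeline never prints its threshold; 0.5 is
the unique value at which a softmax "binary prediction" is unambiguous,
and it is configurable), then largest-connected-component filtering for
the blob and axial-tube classes only.  The paired-tube class is exempt:
its fragments are genuinely non-adjacent across thick slices, and
filtering would discard real structure.  Removed voxels become
`UNLABELED`, not background — the distinction matters because background
is itself a trained class.  Connectivity defaults to 26 (the least
aggressive splitter under strong anisotropy) and is configurable.

## The two adaptation stages

**Stage I — transfer learning.**  Each member is fine-tuned independently
on the labeled target cases at a reduced learning rate with the decoder
frozen (encoder + bottleneck trainable), early-stopped on validation, and
the best-validation snapshot is kept.  The freeze is tested bit-exactly.

**Stage II — self-learning.**  Cycles of label propagation and
retraining: generate pseudo-labels with the current ensemble, retrain
every member from its current weights (no re-initialization, all groups
trainable) on labeled (w = 1) plus pseudo-labeled cases under the partial
Dice loss, and evaluate on validation.  The loop stops when the
validation metric stops improving, capped at `sl_max_iters` (default 5,
matching the typical three-to-five cycles), and returns the
best-validation iteration — with the input models counted as iteration 0,
so the stage can never return something worse than its input on
validation.  The stage-II learning rate is not published; it defaults to
the stage-I rate, the conservative choice for retraining from adapted
weights.  Validation uses mean foreground DSC rather than loss (also
configurable): "best validation performance" is ambiguous, and DSC is the
quantity the evaluation targets.

Ablation arms (`arm_config()`): from-scratch, TL, TL+SL (k = 1, fixed
w = 0.5), TL+ENS (ensemble, fixed w), ENS+H (no TL, source-initialized —
whether this arm initializes from source weights is not fully specified;
source initialization is the reading that isolates the TL contribution),
and TL+ENS+H.  `predict_labels(..., vote = "majority")` adds the
majority-vote variant, with ties broken by the higher ensemble-mean
probability.

## Evaluation

`dsc()` is the plain overlap coefficient with explicit empty-mask
conventions (both empty → 1, one empty → 0, chosen to be monotone and
reported as such).  `abd()` extracts surface voxels as foreground voxels
with a face-adjacent background neighbour (grid boundary counts as
background), measures Euclidean distances between voxel centres in
physical millimetres, and evaluates the symmetric sum-of-minima formula;
it is undefined (NA, flagged, never a crash) when either surface is
empty.  Voxel centres rather than mesh surfaces are used — the published
definition does not say, and voxel centres are the deterministic choice.
Both metrics are verified against brute-force oracles and closed-form
hand computations.

## The phantom generator

The generator emulates what drives the method, not MRI physics: an
anisotropic grid (default 64×64×16 at 1×1×3 mm, preserving the thick
slice ratio), one large ellipsoidal blob, one thin axial tube posterior
to it, two small posterolateral tubes sharing a class (the size hierarchy
that makes the thin structures the hard targets), per-class Gaussian
intensities with a global noise floor, and a source→target shift composed
of a smooth invertible anterior–posterior compression (applied with
linear interpolation to images and nearest-neighbour to labels, so labels
move with the image by construction), a monotone gray remap
`v → 0.7·v^1.5 + 0.25` that compresses contrast, and extra noise.

Defaults and why:

* class means (0.20, 0.55, 0.85, 0.40) with noise sigma 0.08 keep every
  foreground class ≥ 2 noise sigmas from background — learnable by a small
  network, with the paired-tube class the closest to background and hence
  the hardest, mirroring the real task's difficulty ordering;
* structure jitter 0.2: organ sizes and positions vary by tens of
  percent across subjects, and the labeled target set being *small
  relative to anatomical variability* is precisely the regime the method
  addresses; with near-identical cases five labels would saturate any
  baseline;
* deformation amplitude 0.15 of the grid extent stays safely inside the
  invertibility bound (≈ 0.32 for the sinusoidal profile used).

What the phantoms do **not** model: partial-volume blur, bias fields,
inter-reader label noise, tumours, anatomically realistic texture.
Passing the synthetic benchmark therefore demonstrates that the pipeline
*mechanics* (freezing, pseudo-labeling, weighting, selection) behave as
designed and that the adaptation ordering emerges under a genuine
appearance-and-shape shift — not that clinical-grade accuracy transfers.

## Desk-scale choices

The test suite and the synthetic benchmark run on one CPU, so problem
sizes are scaled down and stated here as the package's own choices: unit
tests use 16×16×4 grids with a 2→8-filter network; the stage-I freeze
check uses the 64×64×16 default grid with the 4→32-filter network; the
domain-adaptation ordering benchmark uses 24×24×8 grids, k = 3, a source
cohort of 10 labeled + 2 validation cases, a target cohort of 5 labeled +
10 unlabeled + 5 validation + 10 test cases, and 3 seed replicates.

Training schedules scale with the update budget.  A full-scale run takes
thousands of Adam updates at learning rate 1e-3 (supervised) and 1e-4
(fine-tuning); Adam's per-update displacement is bounded by the learning
rate, so a desk-scale run of ~10²  updates cannot travel the required
distance in weight space at those rates.  The benchmark therefore uses
1e-2 (supervised), 3e-3 (stage I) and 1e-3 (stage II), preserving the
published ordering supervised > stage-I > stage-II; the package
*defaults* remain the published full-scale values.  Epoch budgets
(50 supervised, 20 stage-I, 6 per stage-II retraining, 2 cycles) were
sized for convergence of the supervised arms on phantoms within the
benchmark's runtime; the from-scratch arm in particular is trained to
convergence so that its comparison with transfer learning reflects data,
not budget.

## Numerical conventions collected

* Dice smoothing `eps = 1e-5`, denominator only; background included in
  the class mean by default.
* Instance-norm epsilon 1e-5; He-normal weight init, zero biases, unit
  scales.
* Early stopping: strict improvement of the validation metric;
  reduce-on-plateau halves the learning rate after `ceiling(patience/2)`
  stagnant epochs (the published schedule says only "learning rate
  decay").
* Component-size ties break toward the component whose first voxel comes
  earliest in raster order; majority-vote ties toward the higher
  ensemble-mean probability; argmax ties toward the lower class index.
* Degenerate inputs: constant volumes normalize to all zeros; an
  all-zero mask gives partial-Dice 0 and no gradient; an empty
  pseudo-label pool degenerates stage II to supervised fine-tuning with a
  warning; both-empty masks give DSC 1; ABD with an empty surface is NA.
* All randomness flows from explicit integer seeds (phantoms per case,
  member training per seed, stage-II retraining seeds derived as
  `member_seed + 7919·iteration`).

## Known limitations

The training engine is a compact CPU implementation (im2col + GEMM
convolutions, instance norm, Adam) built for desk-scale grids; it is not
a GPU framework and full-size 184×184×32 training, while functional, is
not its intended use.  Batch size interacts with instance normalization
(normalization is per case, so gradients are batch-size-independent up to
averaging).  The NRRD reader covers scalar 3D raw/gzip files only.  The
phantom benchmark's stochastic ordering assertions hold in expectation
over the pinned seeds; individual replicates can invert neighbouring
arms, as the published per-structure tables themselves do.
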