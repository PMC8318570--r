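---
title: "Multi-modal 3D brain segmentation with uncertainty gating: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal 3D brain segmentation with uncertainty gating: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the segmentation pipeline, the network and its loss, the Monte-Carlo
dropout quality gate, the evaluation metrics, and — because every design
space has gaps — the numerical and methodological choices we made where a
published description leaves room.

## The pipeline

A scan of any modality (T1-weighted MRI, FLAIR, DWI, CT) and any grid is
segmented in five stages:

1. *Affine coregistration* to a user-supplied reference volume.
2. *Cubic-spline resampling* of the registered scan to the network's input
   grid.
3. *Intensity normalization* to the interval [0, 100].
4. *CNN segmentation*: the network emits a softmax quasi-probability map
   $P_s(x)$ for each class $s$, converted to a hard mask by
   $S(x) = \arg\max_s P_s(x)$ (ties, which occur only on exactly equal
   floats, break toward the lower label id).
5. *Back-projection*: the mask returns to the scan's native grid through
   the inverse of the estimated affine, resampled nearest-neighbour so no
   new label values can be invented.

The registration-first design is what makes one trained network usable for
arbitrarily shaped inputs: the network always sees a standard grid.
Normalization happens after registration resampling, matching the order of
the stages above.

## Registration

The affine estimator maximizes normalized mutual information (NMI),
$\mathrm{NMI} = (H_R + H_M)/H_{RM}$, computed from a $32\times32$ joint
histogram of the reference and the transformed moving image. NMI depends
only on the statistical dependence of the two intensity distributions, not
on their agreement, so CT can be registered to a T1-weighted reference —
a requirement for the multi-modal setting. Mechanics:

* 12 parameters (translation mm, rotation degrees, log-scales, shears)
  about the reference's center; rigid subsets available via `dof`.
* A 3-level resolution pyramid (coarse grids via linear down-resampling,
  factors 4/2/1, levels dropped if a grid would fall below 8 voxels per
  axis), Nelder–Mead at each level seeded by the previous one,
  initialization at the identity. The procedure is fully deterministic.
* Overlaps below 50% of the reference are penalized linearly, so sliding
  off the grid can never look attractive; if the final objective fails to
  beat the identity, the identity is returned with
  `identity_fallback = TRUE` and a warning.

On nearly ellipsoidal phantoms a small rotation is close to a symmetry of
the image, so the *rotation parameters* themselves are weakly identified;
what the pipeline relies on — and what the tests measure — is the residual
*displacement* after composing the true and estimated transforms (at the
volume center this isolates the translation error), plus the whole-head
overlap after alignment.

## The network

The segmentation network is a 3D U-Net: $D$ encoder blocks, a bottleneck,
$D$ decoder blocks with skip connections, and a final $1^3$ convolution
with softmax. Each encoder/decoder block is two (conv $3^3$ → batch-norm →
ReLU) operations; encoder blocks end in dropout and $2\times$ max-pooling,
decoder blocks begin with a $2^3$/stride-2 transpose convolution that
doubles resolution and halves channels, concatenate the matching encoder
output, and end in dropout. The bottleneck has no dropout. Feature maps
start at $F$ after the first convolution and double per encoder level
($F, 2F, \dots$; bottleneck $2^D F$). Reference configuration: $D = 4$,
$F = 32$, input shapes 128³ (T1/FLAIR), 160×160×32 (DWI), 96×128×96 (CT),
28 output classes (27 structures + background). All shapes and widths are
configurable; the only structural constraint is that each input dimension
be divisible by $2^D$.

Everything is implemented natively: convolutions as im2col + BLAS GEMM in
RcppArmadillo, pooling/transpose convolutions as direct kernels, batch
norm/ReLU/dropout/softmax and the optimizer in R. The backward pass is
exact (verified against central finite differences at relative error
$\sim 10^{-9}$), and every stochastic element — initialization (He
normal), data order, augmentation, dropout — draws from a single root
seed, so training runs are bit-reproducible.

Choices where the design was open:

* **Dropout type.** Elementwise dropout is the default. We initially used
  spatial (channel-wise) dropout, but on narrow networks it is far too
  destructive a perturbation for Monte-Carlo sampling: dropping one of 8
  feature maps removes entire structures from individual samples, and the
  volume CV saturates near 1 even on clean input, destroying the
  CV-quality relationship. Elementwise dropout (the default dropout layer
  of the major frameworks) perturbs gradually at every width;
  `dropout_type = "channel"` remains available.
* **Skip connections** concatenate channels (classic U-Net); transpose
  convolutions use kernel $2^3$, stride 2; padding is "same" so the output
  grid equals the input grid.
* **Dropout placement**: after each block's conv pair, before pooling.
* **Batch-norm at MC inference** uses running statistics (inference mode);
  only dropout is stochastic. With batch size 1 the "batch" statistics are
  spatial statistics per channel.

## Loss and training

The loss combines a smoothed soft Dice term per class with the categorical
cross-entropy:

$$\mathcal{L} \;=\; -\sum_{s}\frac{2\sum_x P_s(x)T_s(x) + \varepsilon}
{\sum_x \big(P_s(x)+T_s(x)\big) + \varepsilon}
\;-\; \sum_{s}\sum_x T_s(x)\,\log\max(P_s(x),\varepsilon),$$

with $\varepsilon = 10^{-5}$, minimized as written (the cross-entropy term
here is $+\mathrm{CE}$; a perfect prediction approaches $-C$). Writing the
combination with the cross-entropy *subtracted from* the Dice sum inside
one bracket would reward assigning low probability to true classes —
minimizing such an objective diverges — so the package implements the form
above; the two Dice/CE ingredients are equally weighted, which costs
little, and the smoothing $\varepsilon$ appears in numerator and
denominator so a class absent from both prediction and truth contributes a
perfect Dice term and no gradient. Cross-entropy's log is clipped at
$\varepsilon$.

One optimization subtlety: the loss *value* uses the clipped logarithm,
but its *gradient* is taken with respect to the logits through the exact
softmax/cross-entropy identity $\partial\mathrm{CE}/\partial z = P - T$.
Differentiating the clipped log instead yields exactly zero gradient
wherever $P_s(x) < \varepsilon$, so a class whose probability ever
collapses would never receive another cross-entropy gradient — we observed
precisely this failure (small structures permanently dead) before adopting
the exact form.

Training is Adam (learning rate 0.001 by default) for up to 400 epochs
with early stopping when the validation loss has not improved for 100
epochs; the returned model carries the best-validation-loss weights, and
restoring them reproduces the recorded loss to $10^{-5}$. Augmentation
applies one random rigid-plus-crop-zoom transform per volume per epoch to
image (spline) and labels (nearest) jointly; default magnitudes ±5 voxels,
±10°, 10% crop — values we chose, stated here because no standard exists.
Divergence (non-finite loss) aborts with a diagnostic rather than
continuing silently.

## The Monte-Carlo dropout quality gate

At inference the dropout layers stay active and $N = 15$ stochastic
forward passes are drawn (per-sample seeds derived reproducibly from one
inference seed). The final segmentation aggregates the evidence before the
argmax:

$$S(x) = \arg\max_s \sum_{i=1}^{N} P_s^i(x),$$

which for $N=1$ reduces exactly to the deterministic rule. For each
structure the volumes of the per-sample hard segmentations give a mean
$\mu_s$ and a sample standard deviation $\sigma_s$ ($N-1$ denominator),
and

$$CV_s = \sigma_s / \mu_s, \qquad
CV = \frac{1}{|S^+|}\sum_{s \in S^+} CV_s,$$

the mean running over the non-background structures that appear in at
least one sample (absent structures have $CV_s = 0$ by convention and are
excluded from the denominator). A scan is flagged when $CV$ exceeds a
modality threshold. Two conventions deserve a note. First, a "variance"
in a dimensionless ratio must be a standard deviation, which is what we
use; had the population SD been intended, every $CV$ would shift by the
constant $\sqrt{N/(N-1)} \approx 1.035$ at $N = 15$, well inside any
threshold's tolerance. Second, averaging (rather than summing) $CV_s$ is
what makes percent-scale thresholds meaningful. The default thresholds —
1.0% for T1-weighted input, 2.5% for FLAIR/DWI/CT — were calibrated on
clinical data; on other input distributions (including our phantoms, where
clean-input CV sits near 3%) the threshold should be recalibrated, e.g. to
a cohort median, before the flag is interpreted.

## Evaluation metrics

Per structure, with $S_s, T_s$ the one-hot masks of prediction and truth:

* Dice $D_s = 2\sum_x S_s T_s / \sum_x (S_s + T_s)$; empty-in-both is
  defined as 1 (configurable convention, documented).
* Average Dice $D_A$: the arithmetic mean of $D_s$ over the non-background
  structures — reported on the percent scale it is an average, so the
  package divides by the number of structures included.
* Volume-weighted Dice $D_V = \frac{1}{V}\sum_s V_s D_s$ with $V_s$
  measured on the *predicted* mask ($D_V$ is undefined for an
  all-background prediction and reported as a flagged missing value).
* ASSD: surfaces are mask voxels with a non-mask 6-neighbour (the grid
  border counts as outside); distances are Euclidean between voxel centers
  in mm under the anisotropic spacing;
  $\mathrm{ASSD} = (\sum_{a\in A} D_B(a) + \sum_{b\in B} D_A(b)) /
  (|A| + |B|)$, undefined-and-excluded when either surface is empty, with
  the exclusion count reported.

Surface connectivity and center-to-center mm distances are our operational
definitions; the test suite pins every metric to independent brute-force
oracles (set-intersection counts, all-pairs minimal distances) at
$10^{-9}$.

## The synthetic phantoms

The phantom generator stands in for clinical databases that cannot be
shared. A phantom is a set of nested ellipsoids with sinusoidally
perturbed boundaries on a configurable grid: the default layout has 8
structures (cortex shell, white-matter core, two ventricles, thalamus,
putamen, hippocampus, brainstem; extendable to 27 by deterministic extra
blobs), and per-subject geometry seeds jitter centers, axes and boundary
phases. Renderings assign each label a modality-specific mean intensity
plus i.i.d. Gaussian noise (σ = 5 by default) and an optional polynomial
bias field (amplitude 0 by default). The contrast tables encode the
radiological ordering that drives the multi-modal story: T1-like contrast
separates the gray- and white-matter-like structures by ≥ 4 noise SDs; the
CT-like table separates them by ≤ 1 SD. `misalign` and `degrade` produce
the unregistered and corrupted variants the registration and QC
experiments need, always returning ground truth alongside.

What the phantoms deliberately are **not**: anatomically realistic,
physically simulated (no MR physics, no Rician/Poisson noise, no partial
volume), or calibrated to any scanner's intensity statistics. Passing
tests on phantoms demonstrates that the *mechanisms* work — learnability,
registration recovery, the CV–quality anticorrelation — not that any
particular clinical accuracy would be attained.

## Problem sizes used by the tests and the acceptance script

These are the package's reproducibility settings, chosen so the whole
suite runs on a single CPU in well under half an hour:

* Default phantom grid 64³ at 1 mm isotropic. Learning experiments run on
  24³ grids (capacity check: 32³) with $D=2$, $F=8$ networks.
* On grids below ~64³ the default layout's ventricles shrink to a few
  dozen voxels and the two ventricles are intensity-identical twins told
  apart only by position — properties of the invented geometry that
  confound capacity measurements. Small-grid experiments therefore use the
  documented `coarse_phantom_structures()` layout (cortex / white matter /
  one enlarged ventricle), whose structures all stay resolvable.
* The capacity smoke test (overfit one 32³ pair within 200 gradient steps)
  runs with dropout disabled and learning rate 0.003: it probes
  optimization and representational capacity, and regularization noise is
  deliberately excluded from it. The r = 0.2 rate applies wherever MC
  sampling is exercised.
* At width $F = 8$ a minority of He initializations land in an
  irreversible dying-ReLU state: every final-block feature is zero across
  one structure's whole region, leaving no gradient path to revive it (we
  verified that dropout noise, augmentation, Dice-term upweighting,
  learning-rate changes and even tripling the structure's size do not).
  The acceptance script therefore runs the capacity experiment as a
  multi-start — up to three seeded initializations, restarting on
  non-convergence — the same logic as `nstart` in k-means; the reported
  step count is that of the converged run. At the reference width
  $F = 32$ this fragility is not expected, as each block carries 4× the
  feature redundancy.
* The scaling study trains on 2/8/32 phantoms with identical
  hyperparameters and evaluates on 4 fixed held-out phantoms; the QC study
  feeds 12 phantoms across additive-noise degradations (σ = 0…55) to the
  8-phantom model, with the gate threshold set to the cohort median CV.

## Known limitations

* CPU-only; at the reference scale (128³, $D=4$, $F=32$) a forward pass is
  minutes, not the sub-second GPU latency the method achieves elsewhere —
  the implementation targets correctness, testability and moderate sizes.
* The NMI estimator handles affine misalignment only; strongly rotated
  near-symmetric subjects identify the alignment, not the rotation
  parameters (see Registration).
* NIfTI-1 stores the affine in 32-bit floats; world affines round-trip at
  ~$10^{-5}$ relative accuracy (exactly, for float32-representable
  entries).
* The CV gate is a cohort-relative signal; its printed default thresholds
  transfer only to data resembling their calibration distribution.
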