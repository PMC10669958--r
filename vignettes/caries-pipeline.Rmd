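---
title: "Per-tooth caries localization and reader-study evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-tooth caries localization and reader-study evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctCaries)
```

This vignette is the package's own account of its methods: the geometric and
statistical model, the parameters that matter and why their defaults are what
they are, what the synthetic phantoms do and do not emulate, and the numerical
decisions taken where a design was genuinely open.

## The per-tooth localization model

The pipeline assumes the tooth segmentation problem is already solved: a
binary mask per tooth, voxel-aligned with the scan, is an *input* (in clinical
systems it comes from a separate segmentation network; here it comes from the
phantom ground truth).  Caries-sign localization then factors into three
stages.

**1. Geometry normalisation.**  `extractToothVolume()` crops the scan to the
tooth's bounding box expanded by `marginMm` per side, resamples the crop to
isotropic `targetSpacingMm` voxels and resizes it to the fixed `inputShape`.
The margin buys context (neighbouring tooth surfaces are exactly where
approximal lesions sit); the isotropic resample makes the network see a
consistent physical scale regardless of scanner settings; the fixed shape is
a plain requirement of batched convolutional inference.  Every step is
recorded in a `CropTransform` so that `restoreToOriginal()` can put a
prediction back onto the original grid; the tests require the mask round trip
to keep Dice ≥ 0.9 and the physical mask volume to be conserved within 5%.

Order of operations is crop → resample → resize, with trilinear interpolation
for intensities and nearest-neighbour for masks (anything else would produce
non-binary masks).  When the expanded box exceeds the scan it is clipped, not
padded: clipping never invents intensities.  A disconnected mask (multi-rooted
teeth can fragment under resampling) uses the bounding box of the union of its
components.

**2. The network.**  `buildNetwork()` constructs a fully convolutional 3D
U-Net with the following deviations from the vanilla architecture: encoder
levels are connected by stride-2 3×3×3 convolutions rather than pooling;
up-sampling is nearest-neighbour; each decoder block is a 3×3×3 convolution
followed by a 1×1×1 convolution that halves the feature maps; skip
connections pass through additive attention gates; per-level segmentation
maps are up-sampled and summed element-wise into the final logits (deep
supervision); activations are leaky ReLU and normalisation is per-instance
(batch statistics are useless at batch size 2); and a classification head
predicts a tooth-level pathology probability by global average pooling of the
bottleneck features — the deepest point of the decoder path — followed by a
dense layer and sigmoid.

The attention gate follows the standard additive formulation: the skip
features are down-sampled to the gating resolution, both tensors are
projected by 1×1×1 convolutions, added, passed through the nonlinearity, and
projected to a single channel whose sigmoid gives one coefficient per spatial
location.  Coefficients are up-sampled trilinearly and multiply the skip
features, broadcast over channels.  We read "a single scalar per pixel
vector" literally: one coefficient per voxel, not per voxel-and-channel.

Everything — forward pass, hand-derived backward pass, Adam — is implemented
on BLAS matrix products via im2col, with two small compiled kernels for the
memory-bound gather/scatter.  Convolutions feeding instance normalisation
carry no bias: the normalisation subtracts any bias exactly, so such a
parameter would have an identically zero gradient.  The test suite contains a
finite-difference gradient check covering every parameter group, which is the
package's substitute for trusting an autodiff framework.

**3. Post-processing.**  `runPostprocess()` turns raw probabilities into a
final call:

1. recalibrate voxel probabilities (below) and threshold at `probCutoff`
   (default 0.5 on the recalibrated scale);
2. intersect with the binary dilation of the tooth mask
   (`dilationRadiusVoxels`, default 1, ball of the chosen connectivity) —
   this removes predictions sitting inside neighbouring teeth;
3. label connected components (`connectivity`, default 26) and discard
   components with physical volume strictly below `minLesionVolumeCm3`.

We deliberately intersect *before* the volume filter.  With the opposite
order the tooth intersection could shave a surviving component below the
volume threshold, breaking three properties we consider contractual and test
explicitly: the final mask is always inside the dilated tooth, every reported
component meets the volume threshold, and the operation is idempotent on its
own output.

**Recalibration.**  `calibrateThreshold()` sweeps candidate thresholds at
midpoints between sorted distinct predicted probabilities and picks the
maximiser of sensitivity + specificity (the Youden point), breaking ties
toward the lower threshold.  `rescaleProbability()` then maps t\* to 0.5 by
the minimal monotone map with fixed points {0 → 0, t\* → 0.5, 1 → 1} — two
linear pieces.  Any strictly increasing anchor-preserving map would satisfy
the stated requirement; piecewise linear is the least-assuming choice and is
bijective on [0, 1] for every t\* in (0, 1), which the tests check on a grid.

## Tunable parameters

| parameter | unit | default | rationale |
|---|---|---|---|
| `marginMm` | mm | 3 | context around the tooth; covers approximal surfaces of both neighbours |
| `targetSpacingMm` | mm | 0.25 | standard dental CBCT working resolution |
| `inputShape` | voxels | 96×64×64 | fixed network input; long axis gets the 96 |
| `minLesionVolumeCm3` | cm³ | 0.3 | deployed operating value; see limitations |
| `dilationRadiusVoxels` | voxels | 1 | tolerate one voxel of mask/prediction misregistration |
| `connectivity` | – | 26 | most permissive; 6 and 18 available |
| `probCutoff` | probability | 0.5 | the recalibration makes 0.5 the operating point by construction |
| `nLevels` / `baseChannels` | – | 4 / 8 | CPU-trainable at 96×64×64; tests use 3 / 2 at 32³ |
| `learningRate` | – | 1e-3 | Adam default; the desk-scale training checks use 1e-2 |
| `leakySlope` | – | 0.01 | conventional |

The 0.3 cm³ (300 mm³) lesion-volume threshold deserves a flag: it is very
large relative to a whole tooth (≈ 1 cm³), so at this default most plausible
approximal lesions are filtered out.  It is retained as the documented
operating value of the system this pipeline mirrors and is exposed in
`PipelineConfig`; the demo configuration uses a much smaller value so that
phantom-scale lesions survive.

## What the phantoms emulate — and what they do not

`generatePhantom()` builds a row of simplified teeth: a superellipsoid crown
(exponent 4, so slightly boxy) fused to a tapered ellipsoid root, at
configurable intensity levels for background, dentin and enamel.  Lesions are
spheres centred on the mesial or distal surface point of a tooth, intersected
with the tooth, with the radius bisected until the realised volume lands
within 10% of the requested target; they are therefore connected, surface-
anchored and volume-controlled, which is exactly what the pipeline's surface
semantics and volume filter need for testing.  Additive Gaussian noise models
the low signal-to-noise of CBCT; optional oriented streaks give a qualitative
stand-in for beam-hardening artifacts (off by default).  A single RNG stream
per phantom is split into named substreams (geometry, noise, ratings) so each
component is independently reproducible.

What the phantoms do **not** emulate: projection/reconstruction physics,
scatter, partial-volume blur at tissue boundaries, anatomy beyond teeth
(bone, pulp chambers, restorations), or realistic lesion morphology.
Consequently, a network that performs well on phantoms demonstrates that the
*pipeline is trainable and its plumbing is correct* — not that it would
detect caries clinically.  The trainability checks are engineering smoke
tests, not accuracy claims.

`simulateRatingStudy()` draws each observer's binary call from the model's
sensitivity/specificity given the surface truth, then a five-point confidence
score conditional on the call (positive calls draw from {4, 5}, negative from
{1, 2, 3}).  Observers are conditionally independent given the truth; real
readers are not, so simulated inter-observer agreement is a lower bound of
sorts.  The simulation's purpose is parameter recovery: the statistics module
must read back the sensitivities and specificities that generated the data,
within binomial noise.

## Reader statistics: conventions and edge cases

* Binarization: scores 1–3 → absence, 4–5 → presence.
* Consensus ground truth: a surface is labelled only when *all* observers'
  binarized scores agree (provenance `unanimous`); anything else — including
  a missing score — goes to the conflict list, and `mergeAdjudication()`
  requires a decision for every conflict.  Unanimity beats a stray
  adjudication decision (warning, decision ignored).  The consensus defaults
  to the unaided arm's main read; which arm feeds the consensus is exposed as
  a parameter because either choice is defensible.
* Cleaning: surfaces of teeth recorded as `missing` or `excluded` by any
  observer leave the analysis; `restorated` and `support` teeth keep their
  scores.
* Accuracy is (TP+TN)/(TP+FP+TN+FN); kappa's expected agreement comes from
  the row/column marginals; a degenerate single-cell table with perfect
  agreement returns κ = 1.
* Weighted kappa uses w = 1 − (|i−j|/(k−1))^q with q = 1 or 2; quadratic is
  the default.  On a binary scale every weighting collapses to Cohen's κ
  (tested).
* Fleiss kappa requires an equal rater count per item and reports overall and
  per-category coefficients.
* The ordinal ROC uses the four cut points of the five-level scale plus the
  trivial endpoints, AUC by trapezoid; this equals the tie-corrected
  concordance probability, and the tests verify the identity by brute-force
  pair enumeration and against an independent ROC implementation.
* Kappa confidence intervals use the large-sample standard error
  √(p₀(1−p₀)/(n(1−pₑ)²)).

## Numerical choices

* Voxel centres live at (i + 0.5)·spacing; all interpolation maps centres and
  clamps at borders.  Axes are (axial, coronal, sagittal); exported voxel
  intervals are 0-based and half-open.
* Soft Jaccard uses ε = 1e−6, so the empty/empty case counts as perfect
  overlap; cross-entropy clips probabilities to [1e−7, 1 − 1e−7].
* Weight initialisation is He-scaled Gaussian under the config seed; no
  pre-trained weights anywhere.
* Margin-to-voxel conversion rounds to the nearest voxel per axis, treating
  anisotropic sources symmetrically.
* The volume filter removes components *strictly below* the threshold: a
  component of exactly 19,200 voxels at 0.25 mm (300.0 mm³) survives a
  0.3 cm³ threshold; 19,199 voxels do not.
* `resizeToShape()` reaches the fixed input shape by interpolation by
  default; centred pad/crop is available (`resizeMode = "pad_crop"`), and
  both record enough to invert the shape change exactly.
* NRRD headers are written as decimal text at full precision, so spacing
  round-trips bit-exactly; NIfTI stores pixdim as 32-bit floats, so its
  round trip is exact only to single precision (~1e−7 relative).
* Native voxel sizes are treated as free metadata; no assumption is made
  about scanner acquisition spacing.

## Problem sizes used by the tests

Chosen once, as the package's study conditions: training checks run at 32³
voxels (0.4 mm spacing) with a 3-level, 2-channel network, Adam at 1e−2,
batch 2; the overfit check uses 2 phantoms and 200 steps; the generalization
check trains on 20 phantoms (a quarter lesion-free) for 250 steps and
evaluates soft Jaccard on 4 held-out phantoms with 45 mm³ lesions at contrast
0.7 and noise σ = 0.02.  Statistical recovery checks use 20,000 simulated
surfaces; null checks use n = 2,000–5,000.  Geometry checks use 64×64×48
phantoms at 0.3 mm.

## Known limitations

* The imaging half is desk-scale by design: the default 96×64×64, 8-channel
  network trains on CPU but slowly; nothing here is a GPU training recipe.
* The tooth masks are inputs; automatic tooth segmentation and numbering are
  out of scope.
* Lesion surface attribution (mesial vs distal) exists only as phantom ground
  truth; it is not computed from predicted masks.
* DICOM support is read-only and minimal: uncompressed explicit/implicit VR
  little-endian series with consistent slice spacing (a gap raises a geometry
  error).  NIfTI is the interchange format.
* The 0.3 cm³ default volume threshold is documented, not endorsed; see
  above.
* Simulated observers are conditionally independent given the truth, which
  real observers are not; agreement statistics on simulated tables test the
  estimators, not human behaviour.
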