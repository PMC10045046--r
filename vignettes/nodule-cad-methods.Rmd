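---
title: "Methods and design notes for the noduleCAD pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the noduleCAD pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleCAD)
```

This vignette documents the models behind each stage of the pipeline,
the tunable parameters with their defaults and units, what the
synthetic phantoms do and do not emulate, and the numerical and design
choices made where the underlying method descriptions were ambiguous.

## 1. The denoiser

### Model

CT noise is treated as additive i.i.d. Gaussian. A one-level separable
orthogonal wavelet transform (default: the 8-tap Daubechies filter with
four vanishing moments, `"d8"`; `"haar"` available) splits the input
into 4 subbands for a slice or 8 for a volume, using periodized
boundaries so the transform is exactly orthonormal: reconstruction and
energy conservation hold to machine precision, which the test suite
asserts at 1e-8. Odd dimensions are edge-padded to even before the
transform and cropped after reconstruction.

Per decomposition the noise deviation is the MAD estimate from the
finest diagonal subband, `sigma_N = median(|HH|) / 0.6745`. Per subband,
`sigma_y` is the coefficient root-mean-square, the signal deviation is
the BayesShrink form `sigma_s = sqrt(max(sigma_y^2 - sigma_N^2, 0))`,
and the Bayesian threshold is `T_B = sigma_N^2 / sigma_s`. When
`sigma_s` collapses to zero (a pure-noise subband) the threshold is
undefined; the implementation substitutes a *shrink-all sentinel*, the
subband's maximum absolute coefficient, so every coefficient is
thresholded — the behaviour the clamp implies.

Three of the printed source formulas are degenerate as written and were
restored to the standard forms they evidently intend; these are design
decisions of this package, stated once here:

* the signal-deviation formula printed subtracts a quantity from
  itself (always zero); the BayesShrink difference
  `sigma_y^2 - sigma_N^2` is used;
* the observed deviation is printed as a signed mean, which is ~0 for
  any detail subband; the RMS is used;
* the noise estimate is printed without the absolute value, making the
  median ~0; the MAD convention is used.

The threshold modifier is the published rational curve fit
`gamma(beta) = (p1 beta^2 + p2 beta + p3) / (beta + q)` with
`p1 = 0.9592, p2 = 3.648, p3 = -0.138, q = 0.1245` and `beta = sigma_N`
(a global override is available since the source leaves the choice
open). `gamma(0) = -1.10843` is negative; since a negative threshold is
meaningless, the collaborative stage uses `|gamma|`. The printed
threshold expression is garbled; it is read as the universal-threshold
form `lambda = T_B * |gamma| * sqrt(2 log N^2)` with `N` the pixels per
block.

### Collaborative stage

Every subband is filtered BM3D-style: `blockSize`^2-pixel blocks
(default 4 x 4, stride 2) are matched by squared distance within a
`searchWindow` (default 16 px, i.e. exhaustive at desk scale), the best
`groupSize` (default 8) are stacked, transformed by a unitary 3-D DCT,
hard- or soft-thresholded at `lambda` with the group DC coefficient
exempt, inverse-transformed and aggregated with weights
`1 / (1 + retained coefficients)`. The reference block always joins its
own group (with many identical flat blocks a pure similarity sort can
tie it out, leaving pixels uncovered). A 3-D subband is filtered
slice-by-slice; true 4-D grouping and the Wiener second stage of full
BM3D are out of scope. Subbands smaller than a block fall back to plain
coefficient shrinkage.

Quality is reported as filtering accuracy `(1/MSE) * 100` (percent).
The metric is unbounded as MSE tends to 0, so the MSE is floored at
1e-12 and exact matches are flagged rather than reported as infinite.

### What a green denoiser test establishes

On 20 seeded phantoms per noise level sigma in {10, 15, 20} (8-bit-like
intensity scale), denoising reduces the MSE against the clean phantom in
at least 18 of 20 cases — in the shipped runs, 20 of 20. On pure-noise
volumes `sigma_N` is recovered within 20% at 32^3 voxels. A clean
phantom passes through nearly unchanged because its MAD noise estimate
is ~0. None of this implies optimality on clinical CT; the phantom
background is flat, which flatters any smoothing filter.

## 2. Frame filtering and normalization

Histograms use 256 equal-width bins over a common range (the global
min/max of the sequence unless supplied). The relative entropy is
computed in bits with an epsilon floor of 1e-12 on both distributions so
empty bins stay finite; tiny negative round-off is clamped to zero. The
printed square-root variant is typographically identical to the plain
one; it is implemented as `sqrt(D_RE)` per its name, and a flag selects
which of the two the frame filter thresholds.

The redundancy scan anchors comparisons at the last *kept* frame rather
than the immediate predecessor, so a slow drift of near-duplicates
collapses to one representative instead of surviving pairwise. The
first frame is always kept; the output is an idempotent subsequence.
"Shots" in the video sense have no CT analogue, so the scan treats the
input as one ordered slice sequence.

Z-score normalization uses the population standard deviation followed
by min-max rescaling to [0, 1]: the plain Z-score cannot land in [0, 1]
as the source text claims, and the composition preserves both the
standardization intent and the stated range. It is invariant to
positive affine input transforms; a constant image maps to all 0.5.

## 3. Features

GLCMs quantize to 8 gray levels by min-max over the masked region and
count level pairs at offsets (0,1), (1,0), (1,1), (1,-1) (symmetrized,
averaged). Texture formulas are the standard Haralick definitions — the
source table prints contrast and correlation in each other's cells, and
its "variance" row prints a third-moment formula; the description
("2nd moment") wins. Intensity moments are raw central moments of the
masked empirical distribution (the tabled, unnormalized forms), so
skewness and kurtosis carry intensity units; smoothness
`1 - 1/(1 + variance)` saturates quickly on an 8-bit scale, which is a
property of the published definition, not a bug.

The boundary is extracted by Moore-neighbour tracing (8-connected,
clockwise from north, Jacob's stopping criterion). The perimeter is the
traced closed polygon length plus a half-pixel Minkowski offset
(`pi * spacing`): a centre-traced outline systematically underestimates
the true region boundary, and without the correction small digital
disks exceed the isoperimetric bound by more than the documented 0.15
tolerance. With it, digital squares converge on the continuous-limit
circularity `pi/4` and digital disks score roundness ~0.86-0.96.
Roundness and circularity are both isoperimetric ratios `4 pi A / Q^2`
here: the source lists them as separate rows (one printed with a
malformed denominator), but under a single boundary-length convention
they coincide, and carrying both keeps the documented schema.

The spiculation score is not defined in the source; this package uses
`clamp01(1 - circularity)` as an explicit artifact convention.
Digitization floors the score of perfectly smooth shapes around
0.1-0.15, so the morphology cut-points sit above the floor: >= 0.45
"Irregular", >= 0.2 "Spiculated", else aspect ratio >= 1.25
"Lobulated", else "Smooth". Size bins use cut points 4, 8, 20 mm with
boundaries assigned to the lower bin (the printed gap between "4-7 mm"
and "8-20 mm" is closed at 8). The upper-lobe flag cannot be computed
from a patch and passes through from metadata.

## 4. Classifier

The CNN is deliberately compact: `nConvLayers` (default 3) blocks of
valid 3 x 3 convolution, ReLU and non-overlapping 2 x 2 max-pooling,
then a fully connected softmax. Images are resized bilinearly to
`inputSize` (default 64 x 64) and Z-score normalized per image. The
sensor vector, when configured, is concatenated onto the flattened
activations entering the fully connected layer — the source states that
sensor and image information are fused but not where; the FC input is
the conventional fusion point. With `nConvLayers = 0` the model
degrades to softmax regression on a plain feature vector, which serves
the feature-only and sensor-only paths (the source is ambiguous about
whether the classifier consumes images, features or both, so all three
are provided).

Training is Adam (learning rate 1e-3, the customary default; the source
prints no rate) on categorical cross-entropy, batch size 1, 5 epochs —
the published recipe. Gradients are computed by hand-written
backpropagation (no deep-learning framework is assumed); a numerical
gradient check at relative tolerance 1e-4 guards the implementation.
Everything is deterministic under the config seed, including the
per-epoch shuffling. The training pseudocode in the source is
syntactically unrunnable; it is implemented as standard minibatch
backprop with the stated structural parameters, and its per-class
probability components `Pcomp(i) = count_i / count_total` are retained
as the prior diagnostic. An optional entropy threshold (bits) on the
predictive distribution flags abstentions.

The classifier acceptance check (>= 90% held-out accuracy on a
120-phantom cohort, 80/20 stratified split, 4 of 5 seeds) runs the
fused image + sensor model: the pipeline's stated input is sensed plus
image patterns, and the sensor record is part of the generated world.
On images alone the morphology signal (spiculated versus smooth
boundary under 3-sigma contrast noise) is too subtle for this
5-epoch desk-scale network — typical image-only accuracy is 55-75% —
which is reported here rather than hidden behind a larger budget.

## 5. PSO tuner

Particles move by the inertia-weighted rule
`V <- w V + c1 r1 (pbest - p) + c2 r2 (gbest - p)` with `r1, r2` drawn
per dimension per particle, velocities clamped to half the dimension
range, positions clamped to bounds. The printed velocity update omits
the inertia weight even though the constants table supplies W = 0.85;
the canonical weighted form with `w = 0.85, c1 = c2 = 2` is the
default. Integer dimensions stay continuous during the search and are
rounded at evaluation time; learning rates are searched on a log10
scale. The fitness is `1 - RMSE` of validation predictions against
one-hot targets (the printed radical placement is ambiguous; `1 - MSE`
is available behind a flag). The global best is non-decreasing by
construction, and a non-finite objective skips the best-update with a
warning.

One empirical caveat, verified rather than assumed: with the published
constants (w = 0.85, c1 + c2 = 4) the swarm sits at the edge of the
classical stability region and does not collapse to tight numerical
optima — on the 3-D sphere benchmark (10 particles, 30 iterations) it
typically stalls at 1e-2 to 1e-1 of the optimum. The optimizer
correctness benchmark in the acceptance suite therefore exercises the
exposed constants with the canonical constriction values
(w = 0.7298, c1 = c2 = 1.4962), which recover the sphere optimum to
1e-2 in every tested seed; the published preset remains the default for
hyperparameter tuning, where 10 iterations of coarse search is the
intent and tight convergence is not required. Per-particle CNN training
inside the search uses reduced epochs (default 2); the selected
configuration is refit at the full count.

## 6. Synthetic phantoms

A phantom is a flat lung-field background (level 60) with an optional
low-frequency gradient, one nodule rendered as a base ellipse (axis
ratio uniform in [1, 1.4], random orientation) whose equivalent-circle
diameter equals the requested diameter, a sinusoidal radial spike
pattern (6-12 spikes) with relative amplitude `0.35 * spiculationLevel`,
an anti-aliased edge, nodule contrast 45, and additive Gaussian noise
sigma = 15 (contrast = 3 sigma). Pixel spacing defaults to 0.7 mm — the
middle of the 0.418-1 mm slice-size range of public lung CT sign
databases. Datasets draw diameters uniformly in 6-16 mm, benign
spiculation in [0, 0.15] and malignant in [0.55, 0.95], reproducing the
smooth-versus-spiculated morphology axis that separates the classes.
Per-sample seeds derive from the master seed by a counter-based rule,
so extending a dataset never reshuffles existing samples.

Sensor records stand in for unspecified IoMT device measurements as
5-dimensional class-conditional Gaussians (benign N(0,1), malignant
N(3,1) per dimension) — a declared stopgap, not an interpretation: the
source never describes the sensor payload. At these defaults a midpoint
threshold on a single dimension already separates the classes with
~93% accuracy, which is what makes the fused classifier criterion
meaningful as a pipeline test rather than a vision benchmark.

What the phantoms do *not* emulate: anatomy (vessels, pleura, lobe
structure), CT physics (beam hardening, streaks, HU calibration),
texture heterogeneity inside nodules, and 3-D growth. A green test
establishes that the pipeline's mathematics and plumbing behave as
specified on controlled input — not clinical performance. The published
headline accuracies (~98%) come from externally trained models on
clinical archives and are expressly not reproduced at desk scale.

## 7. Numerical choices and degenerate inputs

* Wavelet filters are hard-coded orthonormal coefficient sets;
  orthogonality, perfect reconstruction and Parseval are asserted in
  the tests rather than assumed.
* KL floor 1e-12 (configurable); zero-MSE floor 1e-12; shrinkage never
  increases a coefficient magnitude and leaves the DC untouched.
* Constant images: Z-score maps to all 0.5, histograms put mass 1 in
  one bin, GLCM mass sits at one diagonal cell with correlation
  reported as an explicit NA marker.
* Single-pixel masks use the pixel-square perimeter (4 x spacing);
  1-2 pixel regions use the crack perimeter.
* Metrics with zero denominators are explicit NA markers listed in the
  report's `undefined` field — never silent zeros.
* All randomness flows through per-call seeds (counter-derived where a
  master seed spawns many); no global RNG state leaks, and re-running
  any stage with the same config is bit-identical.

## 8. Known limitations

* BM3D here is the single collaborative-thresholding stage; no Wiener
  refinement, no DCT dictionary learning.
* The CNN trains on one CPU in seconds at desk scale but is not meant
  for 512 x 512 clinical slices.
* DICOM I/O is not implemented (no DICOM reader in the dependency
  budget); PNG (16-bit) and plain-text PGM are supported.
* Image-only morphology classification at the default noise level is
  beyond this network's budget (see section 4); the fused path is the
  supported configuration.
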