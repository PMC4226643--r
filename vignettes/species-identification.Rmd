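---
title: "Morphometric species identification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric species identification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(taxofeat)
```

This vignette is the package's own account of the method: the model and
its assumptions, the parameters that matter, the choices made where the
design was genuinely open, and what the synthetic benchmark does — and
does not — demonstrate.

## The pipeline

A specimen photograph passes through eight preprocessing stages: background
removal, grayscale conversion (luminance weights 0.299/0.587/0.114),
smoothing (3×3 mean), median filtering (3×3), Otsu binarization, contour
tracing, and skeletonization. The denoised grayscale, the binary mask, and
its contour then feed three feature families — six geometric descriptors,
six texture statistics, three moment invariants — and the resulting
15-vector is classified by a one-hidden-layer sigmoid perceptron. The same
preprocessing and extraction code serves both training and recognition, so
a model learned on one batch of images applies unchanged to new ones.

The central assumption throughout is *one specimen per image on a roughly
uniform background*. Nothing in the pipeline handles occlusion, multiple
bodies, or cluttered scenes.

## Preprocessing choices

**Segmentation.** Background removal is rectangle-initialized: background
intensity statistics are estimated from the frame ring outside an
initialization rectangle (default: the full frame inset 2 px per side),
pixels are split by Otsu's threshold on their absolute distance from the
background level, holes are filled, and the largest 8-connected component
is kept. For images that are already segmented — and for all synthetic
tests, where exact ground truth exists — a mask argument bypasses
segmentation entirely. On the default synthetic benchmark the segmented
masks agree with ground truth at a mean intersection-over-union above
0.99.

**Filters.** Kernel sizes are 3×3 for both the mean and the median stage
(configurable via `kernel`), with reflect padding at the borders. The unit
suite pins this exact semantics against a brute-force per-pixel oracle, so
the filter cannot silently drift to a different edge policy. Note the
order matters: an isolated hot pixel is first spread into a low plateau by
the mean stage and then trimmed by the median stage; it is strongly
attenuated (to at most 1/9 of its amplitude) but not erased, which is the
correct behavior of this filter order.

**Binarization polarity.** Otsu's method gives a threshold but not a
polarity. Specimens are interior objects, so the foreground is defined as
the side of the threshold *not* held by the majority of frame-border
pixels. This makes the pipeline indifferent to whether the specimen is
darker or lighter than its background.

**Thinning.** The skeleton is computed by Zhang–Suen two-subiteration
thinning, which preserves 8-connectivity of every component and is
idempotent on already-thin sets. Different published implementations
differ by a pixel or two at line ends; the test suite therefore asserts
the algorithm's defining properties (thinness, subset-of-mask,
component-count preservation against an independent flood-fill count)
rather than byte-equality with any one external implementation. Connected
components are 8-connected throughout; since `EBImage::bwlabel` is
4-connected, the package derives 8-connected labels from it by merging
diagonally touching labels with a union–find pass.

## Feature definitions and their quirks

**Perimeter is a pixel count.** `P` counts boundary pixels (foreground
pixels with at least one background 8-neighbor), not an arc length. On a
digital disk this count runs well above `2*pi*r` because staircase inner
corners are included, so the compatibility `C = 4*pi*A/P^2` of a disk
converges to about 0.64 rather than 1. That bias is harmless for
classification — it is the same for every specimen — but `C` values should
not be read as absolute circularity on the continuum scale. A
`sqrt(2)`-weighted arc-length mode exists behind a flag for users who want
the conventional estimate.

**`C` and `Co` are exact reciprocals**, and both are kept: the feature
vector contract is 15 inputs, and the redundancy is part of that contract.
`C * Co = 1` holds to machine precision by construction and is asserted
for every mask the tests touch.

**Solidity** uses the convex hull of foreground *pixel centers*,
rasterized by exact scanline clipping with boundary ties counting as
inside. Filled convex digital shapes (rectangles, diamonds) score exactly
1. Note that very small concave-looking sets can also score 1 — a 5-pixel
cross *is* the digital diamond of radius 1 — so solidity only becomes
informative for concavities larger than one pixel.

**Texture.** First-order statistics are the mean and variance of the
gray-level histogram of the masked region (the histogram is kept on
integer levels 0–255). The co-occurrence matrix uses one offset only:
distance 1 pixel along the down-right diagonal `(+1, +1)`, i.e. the −45°
direction in image coordinates, both pixels inside the mask, *not*
symmetrized, with intensities quantized to `levels = 16` bins spanning the
masked min–max range. Entropy uses the natural logarithm. All of these are
configurable, and `levels` is stored with the trained model because the
features depend on it. Quantizing over the masked range makes the four
co-occurrence features invariant to adding a constant to all intensities;
it also means they are *contrast-normalized*, which suits museum
photographs of varying exposure.

A single-offset matrix is directionally anisotropic by definition: under a
quarter-turn rotation of the image the `(+1, +1)` pair set becomes the
anti-diagonal pair set, so the four co-occurrence features are preserved
exactly only for textures whose diagonal and anti-diagonal pair multisets
coincide (for instance mirror-symmetric textures, which is how the
invariance suite exercises the property). Rotation-averaged multi-offset
matrices would remove the anisotropy but are deliberately out of scope;
specimens in collections are photographed in standard orientation.

**Moments.** Raw moments `m_pq = Σ x^p y^q I(x, y)` (x = column,
y = row, 0-based, pixel area 1) and central moments `u_pq` are computed to
order 3 on the binary mask by default; grayscale weighting is available.
The first Hu invariant is computed from scale-normalized central moments,
`phi1 = (u20 + u02)/u00^2`, which is invariant to translation, rotation
and scale — the property that motivates using it at all. A raw-moment
reading `m20 + m02` exists behind `hu_mode = "raw"` for comparison, but it
is not translation invariant and is not the default. The two affine
invariants are normalized explicitly by powers of `u00`:

```
I1 = (u20*u02 - u11^2) / u00^4
I2 = (u30^2*u03^2 - 6*u30*u21*u12*u03 + 4*u30*u12^3 + 4*u21^3*u03 - 3*u21^2*u12^2) / u00^10
```

Every term of each numerator has the same total moment order — the
consistency that makes the ratios affine invariant; the implementation is
checked against translation, 90° rotation, 3× scaling and a 0.3 shear on
smooth rasterized blobs. `I2` is built from third-order moments only, so
it vanishes identically on point-symmetric shapes; it is checked at the
5% level on an asymmetric egg-shaped fixture where it is nontrivial.
Discretization noise dominates `I2` for regions below roughly 3000 px, a
known limitation of third-order invariants on small rasters.

## The classifier

A 15-`h`-`m` network, logistic sigmoid in both layers, trained by *online*
stochastic gradient descent on squared error: one pattern presentation per
"generation", patterns drawn cyclically with the order reshuffled each
pass, weights initialized uniform(−0.5, 0.5) from the seed. The analytic
gradients are verified against central finite differences at relative
error below 1e-6, and training is bit-reproducible given the seed.
Momentum is available but defaults to 0 (plain gradient descent).

**Feature standardization.** The 15 features span six orders of magnitude
(area in thousands of pixels next to probabilities below 0.01); a sigmoid
network cannot train on such inputs. Features are therefore z-scored with
the training-set mean and standard deviation, and the scaler is stored in
the model and re-applied at prediction time, so the model consumes raw
feature vectors transparently. Constant features receive unit scale
rather than dividing by zero.

**Prediction** reports the argmax species (ties to the lowest index), the
raw sigmoid outputs, and the thresholded binary vector (step at 0.5) with
a confidence flag when no output clears the threshold.

Reference training configurations pair learning rates of 0.1–0.5 with
50,000–140,000 generations and 35–300 hidden neurons depending on the
number of species; the packaged default (`train_config()`) is lr 0.1,
50,000 generations, 60 hidden neurons, which suits data sets of a few
dozen species.

## Evaluation protocol

Train/test splits are stratified per species (rounding keeps at least one
sample on each side; a species with a single specimen is an error), at
training fractions 60/70/80/90% by default. Because single splits of small
test sets are noisy, every reported rate is the mean over a configurable
number of seeded repetitions (default 3), with the seeds logged in the
report. The success rate is the percentage of test specimens whose argmax
prediction matches their label, and is re-derivable from the reported
confusion matrix. A hidden-neuron sweep trains one model per candidate
size under the same seed policy and writes a CSV and plot.

## The synthetic benchmark: what it emulates, and what it does not

The generator renders each "species" as a parametric silhouette — an
ellipse whose boundary radius is modulated by Fourier harmonics 2–4 —
filled with a striped, noisy interior on a near-uniform light background,
with per-individual jitter on axes (5%), perturbation amplitudes,
intensity (sd 6 gray levels), rotation (sd 8°) and position (±3 px).
This emulates the *structure* of the real problem: species that differ in
size, elongation, boundary waviness, and interior patterning, with
intra-species variation on all of those, plus a segmentation step that has
to find the body before anything can be measured. The `confusable_pair()`
constructor clones a species with a controlled shift in a single shape
axis, reproducing the near-identical congener situation in which
morphometric classifiers degrade toward chance.

The default `benchmark_specs()` separation was calibrated once so that the
10-species × 30-image benchmark sits in the low-to-mid 90s success range
rather than at ceiling — informative about learning-curve effects, with
every adjacent species pair overlapping partially in each individual
feature. Images are 96×96 px; at that size a full benchmark run
(300 renders, 300 end-to-end extractions, nine 50,000-generation
trainings) completes in about a minute on one CPU, which is the problem
size the packaged tests and the acceptance script use.

What the benchmark does *not* show: performance on real photographs.
Synthetic backgrounds are clean, illumination is flat, silhouettes are
star-convex, and the texture model is far simpler than scale patterns or
leaf venation. Passing the packaged benchmark demonstrates that the
pipeline is implemented correctly and that the feature set separates
shape/texture differences of the modeled kind — not that any particular
accuracy will be achieved on a museum collection. Benchmark rates also
carry sampling noise of roughly ±2–3 percentage points across seeds at the
90/10 split (30 test images); comparisons between split fractions within
a single seed should be read with that in mind.

## Numerical and degenerate-input policy

* Empty masks, constant images (no Otsu threshold), single-pixel
  co-occurrence domains, and single-species training tables raise errors
  with specific messages rather than returning degenerate values.
* `0·log 0 := 0` in the entropy sum.
* Argmax ties in prediction break to the lowest output index,
  deterministically.
* The sigmoid is evaluated in a branch-split form that cannot overflow.
* Quantization maps the masked minimum to bin 0 and the maximum to bin
  `levels − 1`; a constant masked region maps everything to bin 0.
* Degenerate jittered individuals (non-positive axes) are resampled up to
  100 times before erroring.
* Multi-component masks are measured as the union by default; a
  largest-component option exists in both segmentation and geometry.

## Known limitations

* The co-occurrence features are single-offset and therefore
  orientation-sensitive (see above); specimens should be presented in a
  consistent orientation, as they are in collection photographs.
* The perimeter definition biases `C`/`Co` relative to their continuum
  values.
* The background model assumes the frame ring is background; a specimen
  touching the image border will confuse the default segmentation (supply
  a mask or a tighter rectangle in that case).
* Squared-error training of sigmoid outputs is the classical formulation
  and is retained deliberately; it converges more slowly than
  cross-entropy on confident errors.
* With 30 images per species the benchmark's split rates carry the
  sampling noise quantified above; conclusions about protocol-level
  trends should average over seeds.
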