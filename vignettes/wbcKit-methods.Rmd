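---
title: "Methods: ellipsoidal colour segmentation and 20-feature classification of white blood cells"
author: "wbcKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ellipsoidal colour segmentation and 20-feature classification of white blood cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbcKit)
```

# The problem

A differential blood count tallies the five white-blood-cell types
(lymphocyte, monocyte, basophil, eosinophil, neutrophil) in a stained
smear. Automating it from microscope images takes three stages: segment
one leukocyte from the background, summarise it by a small feature
vector, and classify that vector. `wbcKit` implements all three stages
plus a synthetic smear generator that makes every stage testable with
exact ground truth.

# Colour model

All colour reasoning happens in HSI space. The package uses the
Gonzalez–Woods arccos chromatic-angle model throughout: hue in degrees in
$[0,360)$, saturation $S = 1 - \min(R,G,B)/\mathrm{mean}(R,G,B)$ and
intensity $I = (R+G+B)/(3\cdot 255)$, both in $[0,1]$. Achromatic pixels
take hue 0 by convention, which makes the conversion total and
deterministic. No quantisation is applied to H, S or I.

The choice of scaling matters because the published discriminating
regions for the two stain protocols (`presetRegion(1)` and
`presetRegion(2)`) come without a stated scaling; their constants (hue
centre 6.042, semi-axes up to 56.8) cannot be reverse-engineered onto a
unique convention, and their rotation matrices are not orthonormal at
printed precision (row 1 of preset 1 has norm ≈ 1.033). The presets are
therefore shipped verbatim, tagged `"published-unknown"`, and
`classifyPixels()` warns when a region's tag differs from the image's.
Regions fitted by this package always carry `"gw-degrees"`.

# The discriminating region

Stained leukocyte tones cluster inside a rotated ellipsoid in HSI space.
`fitRegion()` recovers it by principal component analysis: rows of the
rotation matrix $R$ are the covariance eigenvectors (descending
eigenvalue; each row's sign fixed so its largest entry is positive, which
makes $R$ unique), the centre is the rotated sample mean, and a pixel
$x$ is inside when

$$\sum_{k \in \{H,S,I\}} \frac{((Rx)_k - C_k)^2}{r_k^2} \le 1 .$$

The semi-axes are not prescribed by the source method, so the package
uses a reproducible quantile rule: $r_k$ starts at the
$q$-quantile ($q = \mathrm{coverage}^{1/3}$) of the absolute centred
projections on axis $k$, and a single global factor found by bisection
rescales all three so the fraction of fitting samples with membership
value ≤ 1 hits the requested coverage within 0.5%. Coverage defaults to
0.975. Hue is treated as a linear scalar during PCA — adequate for
stains whose hues stay away from the 0/360 wrap; tones straddling the
wrap would need re-centring before fitting, which the package does not
do.

# Segmentation

`segmentCell()` composes HSI conversion, per-pixel membership
thresholding, and morphological refinement. Raw masks are broken and
noisy, so `refineMask()` applies, in order: 3×3 dilation, 3×3 closing, a
7×7 median filter, hole filling, then keeps only the largest 8-connected
component. The 7×7 median window is fixed by the method being
reproduced; the 3×3 box elements are the smallest standard elements that
close single-pixel breaks, and all sizes are arguments. Whether holes
are filled before or after the median filter is a free choice
(`fillHolesFirst`); the default fills after. Keep-largest implements
small-region removal under the assumption of one cell of interest per
frame; the runner-up components are discarded, not reported.

Segmentations are scored by pixel-level sensitivity
$tp/(tp+fn)$ and specificity $tn/(tn+fp)$. A rate whose denominator is 0
is defined as 1 (nothing to find is vacuously found); this convention
only triggers on degenerate masks.

# Features

Twenty features per cell, frozen in the order `Area`, `Length_var`,
`Comp`, `Hue_var`, `Saturation_var`, `Intensity_var`, `LDP_19` …
`LDP_196` (`featureNames()`), versioned as `wbc-features-v1` so trained
models stay portable.

* **Geometry.** `Area` counts mask pixels. `Length_var` is the
  population variance (1/N form) of the distances from boundary pixels
  to the foreground centroid. `Comp` is perimeter²/area with the
  perimeter estimated as the boundary-pixel count. A boundary pixel is a
  foreground pixel 4-adjacent to background or the image edge: with an
  8-adjacent definition the diagonal staircase of a digital disk almost
  doubles the count and a disk would score *less* compact (≈19) than an
  equal-area square (≈15), inverting the feature's purpose; under
  4-adjacency the expected ordering disk < square < elongated rectangle
  holds at any practical area.
* **Colour.** Population variances of H, S and I over the cell pixels,
  hue treated linearly in degrees.
* **Texture.** The local directional pattern (LDP): each pixel's 3×3
  neighbourhood is convolved with the eight canonical Kirsch masks
  (rotations of `[[-3,-3,5],[-3,0,5],[-3,-3,5]]`), and the bits of the
  three directions with the largest *absolute* response are set —
  magnitude ranking, as is standard for this descriptor; ties break
  toward the lower direction index so codes are deterministic. Valid
  codes have exactly three of eight bits set — $\binom{8}{3} = 56$
  codes between 7 and 224, an inclusive index range of 218 histogram
  bins. Codes are computed on the ITU-R 601 luma of the crop, restricted
  to in-mask pixels so texture reflects the cell, not the background
  (`maskOnly = FALSE` gives full-crop labelling). The feature vector
  keeps the 14 bins {19, 25, 35, 38, 49, 50, 70, 76, 98, 100, 137, 140,
  145, 196} — the bins whose average raw count exceeded 400 on the
  60-image corpus the method was developed on. That list is not
  re-derivable without the corpus and is hard-coded as the default;
  `selectProminentBins()` re-derives such a list from new data, with the
  threshold applied to average counts by default (a per-image variant is
  available since the original rule is ambiguous on this point).

All features are invariant to translating the cell inside the frame.

# Classifiers

All three consume the 20-feature vector and emit one of five labels.
The MLP and SVM z-score features with training-split statistics; the
HRCNN min-max scales to $[0,1]$. Each classifier stores its fitted
transform, so prediction takes raw features.

**MLP.** Architecture 20×12×10×5 (437 trainable parameters), logistic
hidden units, softmax readout, full-batch backpropagation on
cross-entropy with momentum 0.9, learning rate 0.3, 2000 epochs by
default; weight initialisation is the only randomness, so a seed makes
training bit-reproducible. The epoch cap is the stopping rule; there is
no early stopping.

**SVM.** Radial-basis-kernel C-classification with one-vs-one voting
(default $\gamma = 1/20$, $C = 10$); the number of basis functions and
their centres are set automatically by the support vectors, whose count
is reported.

**HRCNN.** The hyperrectangular composite neural network is a two-layer
network whose $j$-th hidden node computes
$net_j(x) = \sum_i f((M_{ji}-x_i)(x_i-m_{ji})) - n$ with the hard
threshold $f(y)=\mathbf{1}[y \ge 0]$, firing exactly when $x$ lies in
the closed box $[m_j, M_j]$; the class output
$f(\sum_j Out_j(x) - \eta)$ fires when any box contains $x$. Any
$\eta \in (0,1)$ behaves identically because hidden outputs are binary;
the default is 0.5. The original training algorithm is only cited, so
the package reconstructs it as sequential covering: visit each class's
points in order, merge a point into the first box whose minimal
expansion to include it swallows no other-class point, else open a
degenerate box at the point. On consistently labelled data this reaches
100% training accuracy by construction (a measured property, not an
aspiration). A best-fit variant (merge into the box with smallest
volume growth) was evaluated and gave no held-out improvement, so the
simpler first-fit rule stays. Inference conflicts are resolved
deterministically: among firing classes the smallest containing box
wins (most specific rule); if none fires, the class of the box with the
smallest summed squared per-feature violation in scaled units wins.
Trained boxes read out as crisp If–Then interval rules
(`hrcnnRules()`); re-parsing rules reconstructs the fire/no-fire
behaviour exactly, and reproduces predictions exactly when the
original min-max scaling is supplied (it defines the metric of the
no-fire fallback).

# Synthetic data

`generateScene()` paints a pale jittered background, rasterises ellipse
cells whose tones are drawn from a tone ellipsoid (default: an
axis-aligned purple-stain region at hue 280° ± 35, S 0.5 ± 0.18,
I 0.38 ± 0.14) truncated at a membership quantile, and optionally adds
cell-tone speckles anywhere in the frame and red granule disks inside
cells — the failure mode of heavily granulated basophils, whose
granules fall outside the nuclear-tone region and erode the detected
mask. Tones are sampled by rejection from a truncated Gaussian in the
region's rotated coordinates and re-checked after 8-bit quantisation,
so every emitted cell pixel genuinely satisfies the membership bound.
Scenes are bit-exact functions of their spec and seed.

What the generator does *not* emulate: chromatic aberration, uneven
illumination, touching cells, red blood cells and platelets, nucleus /
cytoplasm substructure, and stain variability beyond the tone
ellipsoid. Passing tests on synthetic scenes therefore validate the
machinery (membership thresholding, morphology, feature algebra,
classifier contracts), not clinical performance on real smears.

`generateFeatureDataset()` builds labelled 20-feature vectors as five
Gaussian clusters whose centroids sit on orthogonal latent axes exactly
`separation` within-class standard deviations apart, mapped affinely to
plausible feature scales (areas near 3000 px, LDP frequencies near
0.06) and clipped to valid ranges. `separation = 0` gives
chance-level (~20%) classes; `separation = 5` gives a well-separated
but not trivial problem — the Bayes-optimal error is roughly 2.5%.

# Study sizes and numerical choices

Tests run at deliberately small, fixed sizes: scenes of 120×120 px,
region fits on 5000–10000 samples, classifier contracts at 50
vectors/class. For the held-out class-recovery study (all three
classifiers ≥ 0.95 accuracy at 5σ separation) the training size is 200
vectors/class with an independent 200/class evaluation draw: the
covering-based HRCNN generalises by nearest-box distance and needs a
denser sample of each class's support than the margin-based SVM or the
MLP — at 50/class it plateaus near 0.93, at 200/class all three sit at
0.95–0.97.

Other numerical choices: coverage bisection stops at ±0.5% or 60
halvings; eigen-decomposition uses the symmetric solver; membership is
evaluated in double precision with no clamping; JSON model and region
files serialise at 17 significant digits so doubles round-trip exactly.

# Known limitations

* Hue is linear, not circular, in both fitting and variance features.
* The published preset regions cannot be applied to this package's HSI
  convention with any guarantee; they are data, not defaults.
* One cell per image: multi-cell frames keep only the largest
  component.
* The HRCNN covering reconstruction matches the documented training
  contract (perfect training-set recall) but is not verified against
  the original algorithm's unpublished details.
* Granule-degradation behaviour is asserted qualitatively (monotone
  sensitivity decrease), not against any quantitative benchmark.
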