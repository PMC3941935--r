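---
title: "Vascular-bundle morphometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular-bundle morphometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`vbmorph` quantifies a leaflet cross-section of date palm by nine
vascular-bundle descriptors and classifies the cultivar with a small
multilayer perceptron. This vignette records the model, the
assumptions, and the design decisions that were genuinely open — the
reference documentation of each function carries the contracts.

## Preprocessing chain

Fluorescence cross-section images (DAPI-type filter) show vascular
bundles with high contrast in the blue channel, so the chain is: blue
channel → optional linear brightness/contrast rescale (identity by
default; the original workflow adjusted these manually) → threshold →
small-particle removal → outer-boundary trace of the largest component
→ periodic B-spline smoothing.

Numerical conventions, chosen to make every step exactly testable:

* **Threshold**: Otsu's exhaustive between-class-variance sweep by
  default, with a fixed manual level as override. A pixel is foreground
  iff intensity ≥ threshold.
* **Pixel-polygon convention**: pixel (row *i*, col *j*) is the unit
  square [j−1, j] × [i−1, i]; the traced boundary runs along pixel
  edges with the interior on its left, so the shoelace area of the
  polygon equals the component's pixel count for hole-free components.
* **Connectivity**: foreground components are 8-connected; at diagonal
  "pinch" vertices the trace takes the right-most turn, which carries
  it across into the diagonal neighbour so one component yields one
  outer loop. Which convention the original LabVIEW software used is
  not stated anywhere; pixel-level parity with it is not claimed.
* **Particle removal**: the original software's proprietary "particle
  remove" filter is replaced by a documented rule — delete every
  8-connected component with area < `min_area` (default 64 px). Same
  intent (debris removal), testable semantics, idempotent.
* **Smoothing**: a periodic uniform cubic B-spline with 18 control
  points (midpoint of the working range 15–20) is least-squares fitted
  to the traced polygon under chord-length parameterization and
  resampled at 512 points. Three iteratively-reweighted passes (Cauchy
  weights on residuals scaled by the median absolute deviation) follow
  the initial fit: the point of this smoothing step is to suppress
  hair-like excursions, and a plain least-squares fit lets a single
  10-px spike deflect the curve by about 1 px, whereas the reweighted
  fit holds the deviation well below that while leaving spike-free
  contours essentially untouched (deviation < 0.1 px on a sampled
  circle).

## The nine descriptors

Minor-bundle (MnVB) distribution, all normalized by the baseline
length (the distance between the two major-bundle rectangle centres),
hence invariant under rigid motion and uniform scaling:

* **Number** — count of MnVBs between the major bundles;
* **Ratio** — summed unsigned perpendicular distances of MnVB centres
  to the *infinite line* through the baseline, over baseline length.
  Whether the original definition clipped perpendicular feet to the
  segment is unstated; the unclipped line distance is used (it is the
  natural reading of "perpendicular line length") and this choice is
  flagged here.
* **Ratio2** — summed distances to the baseline midpoint, over
  baseline length;
* **Salesman ratio** — length of the shortest closed tour through all
  MnVB centres, over baseline length. Instances with ≤ 13 points are
  solved exactly by Held–Karp dynamic programming, which returns the
  identical optimum to full permutation enumeration at a fraction of
  the cost (the original enumeration ran under a minute at twelve
  points and was truncated at five minutes beyond). Larger instances
  use nearest-neighbour construction plus 2-opt improvement until a
  local optimum or the time budget (default 300 s, matching that
  truncation; tests use ≤ 1 s — on scenes of this size 2-opt converges
  in milliseconds).

Major-bundle (MjVB) shape, from the smoothed contour:

* **Form factor** 4πA/P² — 1 for a circle, < 1 otherwise
  (isoperimetric inequality; asserted with a 10⁻³ discretization
  allowance);
* **Aspect ratio** length/width and **Rectangularity**
  length·width/P, where length ≥ width are the sides of the
  minimum-area oriented bounding rectangle (rotating calipers over the
  convex hull). The original manual rectangles were axis-aligned on
  roughly axis-aligned bundles; the oriented box generalizes this
  reproducibly. Rectangularity is kept exactly as printed even though
  it has pixel units; classifier standardization absorbs the scale.
* **Eccentricity** √(1 − (b/a)²) of the fitted ellipse. The printed
  formula in the source text is typographically garbled; this standard
  form is fixed by its stated anchors (0 for a circle, 1 in the
  parabolic limit).
* **Residual** — RMS approximate orthogonal distance of contour points
  to the fitted ellipse. The ellipse is the direct least-squares conic
  fit with the 4AC − B² = 1 ellipse constraint (stable block
  decomposition). "Residual error" is not defined in the source; the
  Sampson distance (algebraic value over local gradient norm) is used
  because it tracks true geometric distance to first order — with
  Gaussian boundary noise σ the residual reproduces σ within 20% — and
  it is *not* normalized by contour size (the original's behaviour
  here is unknown; the choice is documented and stable).

When both major bundles of a section are annotated, their five shape
features are averaged (configurable to first-only); the two bundles
are biological replicates within a section and averaging uses all
annotated structure.

## Classifier

A multilayer perceptron with bias terms: 9 inputs → 10 tanh hidden
units → K softmax outputs (K = number of cultivars), trained on the
total cross-entropy −Σ ln p(true class), with inputs standardized
((x − mean)/sd, sample sd, training rows only — a constant training
column is an error, not a silent drop).

The original network was trained by a commercial package specified
only as "batch mode" with "stopped when no error reduction occurs
anymore after weights adjustment". Full-batch gradient descent with
backtracking line search is used because it *provably* satisfies that
description: each iteration tries the initial step (0.5) and halves up
to 30 times until the loss strictly decreases; if no step in the
schedule decreases it, training stops. Additional stops: relative
improvement < 10⁻⁸, or 5000 iterations. Weights initialize uniformly
in [−0.5, 0.5] from the run seed. The loss trajectory is therefore
strictly decreasing by construction, and the analytic backpropagation
gradient is checked against central finite differences (h = 10⁻⁶) to
below 10⁻⁶ relative error.

**Cross-validation.** "Tenfold cross-validation" is implemented as 10
repeated random subsampling runs — for each run every sample is
assigned to training independently with probability 0.7 and a fresh
network is trained — following the source's own description of groups
"picked up again randomly" each run (its one reported realized split
was 63/85 = 74.1% training under such random assignment). This is
*not* disjoint 10-fold; a standard k-fold mode exists behind
`mode = "kfold"`. The partition is non-stratified, matching "divided
randomly"; whether the original stratified by cultivar is unknown.
Percentages are reported to one decimal, half-up.

**Variable importance.** The commercial package's importance algorithm
is undocumented, so permutation importance is substituted: the raw
importance of a feature is the mean increase in total cross-entropy
over shuffles of that column, and the normalization (largest value =
100%) matches the original's reporting. Exact parity with the original
importance table is not claimed — beyond the algorithm, it would
require the 85 biological samples, which were never deposited.

## Synthetic scenes

No image data are deposited, so the generator is the test bed for
everything downstream. It emulates what the stained cross-section
shows: two bright elongated MjVB blobs (noisy ellipses, optionally
with hair-like spikes, elongated across the blade) whose centres are a
class-specific distance apart, flanking a row of small MnVB blobs
whose centres are jittered along and scattered perpendicular to the
baseline; signal lives in the blue channel over Gaussian background
noise (sd 5 on a 1024 × 512 8-bit canvas). The ground truth —
rectangles fitting the noise-free ellipse extents, oval centres, true
contours, class label — is returned exactly, and all randomness flows
from one root seed through per-scene derived seeds.

The five default class specifications reuse the five cultivar names
and differ in MnVB count range, scatter, baseline length and MjVB
elongation; one class (hewlat_al_jouf) draws more than twelve minor
bundles so the heuristic tour branch is exercised, as that cultivar
did in the original study. The class counts of the default cohort
(14, 22, 17, 20, 12 — 85 scenes) reproduce the original per-cultivar
sample sizes. Real inter-cultivar effect sizes are unknown; the
defaults are calibrated once for separability (standardized class-mean
distances ≥ 2) and testability, not biological fidelity. Consequently
a green end-to-end test establishes that the pipeline *recovers
class structure that is present* (≥ 90% mean testing accuracy on this
stated world); it does not establish that real cultivars are this
separable, nor reproduce the original 89.1% (which the suite verifies
only as the arithmetic mean of the ten printed per-run accuracies).
The generator also does not emulate tissue texture, epidermis or
optical blur, so thresholding on synthetic images is easier than on
micrographs.

`generate_cohort()` extracts features from the ground-truth
annotations and true contours directly (the annotation path is the
authoritative input route of the semi-automatic workflow); the raster
route — render, threshold, trace, smooth, fit — is validated
separately on rendered blobs, where the fitted ellipse axes come back
within 5% of the specified semi-axes.

## Degenerate inputs and numeric guards

Coincident rectangle centres (zero baseline), empty masks, contours
with fewer than 3 points or zero area, fewer than 6 distinct points or
collinear input to the ellipse fit, constant feature columns, empty
classes, and a single-rectangle scene are all hard errors naming the
offender. Empty MnVB sets give (0, 0, 0, 0) feature values; tours are
0 for < 2 points and twice the pairwise distance for 2. Softmax is
computed with the row-max subtracted; cross-entropy clamps
probabilities at 10⁻¹², random splits resample with an incremented
seed if a side comes out empty.

## Image I/O

The package reads and writes portable anymaps (PGM/PPM, ASCII and
binary, maxval 255) natively and accepts in-memory arrays from any
reader via `raster_image()`. PNG/TIFF readers are deliberately not a
dependency — no such R package is available in the supported
environment — so micrographs should be converted to PNM (e.g.
`convert img.tif img.ppm`) or passed in as arrays.

## Known limitations

* Largest-component selection handles one bundle per mask; scenes are
  segmented per-bundle, not jointly.
* The heuristic tour is a 2-opt local optimum, not certified optimal
  (nor was the original's truncated enumeration); on checkable sizes
  it stays within 10% of the Held–Karp optimum in tests.
* Training is deterministic gradient descent from one seed per run —
  no restarts, no hyperparameter search (out of scope).
* Synthetic separability is by construction; claims about real
  cultivars require real sections.
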