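---
title: "Hybrid retinal vessel segmentation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid retinal vessel segmentation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Fundus photographs show retinal blood vessels as dark curvilinear
structures on a brighter, unevenly illuminated background.  Vessel
caliber spans an order of magnitude, and contrast falls with caliber:
large arterioles and venules are easy to threshold, the thinnest
capillary-scale vessels sit barely above the noise floor.  A single
global rule therefore cannot segment both.  `retiseg` implements a
hybrid strategy that treats the two regimes separately:

1. **Large vessels by adaptive local thresholding.**  The green channel
   (best vessel/background contrast; vessels dark) is normalized by
   subtracting it from a background estimate — a 25 × 25 pixel median
   filter of the image — so vessels come out *bright*.  A pixel enters the
   binary retinal image when it exceeds its local mean by an offset.
   Connected components with area above the minimum grain size *T* = 100
   are large-vessel candidates.  Because the optic-disc rim mimics a
   vessel edge, candidates near the disc (located as the intensity
   centroid of the brightest 1 % of a smoothed copy) are kept only where a
   horizontal or vertical gradient profile shows the *two-sided* signature
   of a dark bar: a local gradient minimum followed by a local maximum
   within the maximum vessel width.  The same extremum-pair rule then
   refines all candidates, filling vessel interiors the threshold missed.

2. **Thin-vessel fragments by classification.**  What remains of the
   binary image — thin-vessel fragments mixed with noise specks — is
   classified pixel by pixel with a soft-margin RBF support vector
   machine.  Each residual pixel gets a 12-dimensional feature vector
   built from 8 oriented line detectors of length *l* (22.5° apart): the
   mean and standard deviation of intensity along the best-aligned
   (minimum-mean) direction D1, and the absolute differences of both
   statistics between the worst direction D2 and D1 — computed on the gray
   image, on an undecimated one-level Haar wavelet modulus, and on a
   curvelet-style directional modulus.  Along a vessel the D1 profile is
   uniformly dark while D2 mixes vessel and background, so the difference
   features are large; on noise all directions look alike.  Features are
   min–max scaled to [−1, 1] on the training extrema.  Class costs are
   asymmetric: noise mislabeled as vessel seeds spurious growth, so the
   noise class carries a tenfold cost (C2 = 10 against C1 = 1), and the
   decision threshold is tightened until at most 1000 pixels per image
   survive.

3. **Thin vessels by tracking growth.**  The classified segments are
   grown from their endpoints.  The Hessian of the green channel at scale
   σ = 1.5 px (Gaussian-derivative convolution) has, on a dark vessel,
   a strongly positive eigenvalue λ1 across the vessel and λ2 ≈ 0 along
   it.  Each growth step moves one pixel along the average of the local
   D1 direction and the Hessian ridge direction, re-centers the candidate
   onto the λ1 crest, and continues only while λ1 > λ1min and |λ2| <
   λ2max.

The final mask is the union of the refined large vessels and the tracked
thin vessels, and evaluation (sensitivity, specificity, accuracy) is
restricted to the field of view.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `median_window` | 25 | px | background median filter window |
| `thresh_window` | 25 | px | local-mean window of the adaptive threshold |
| `thresh_offset` | 0.022 | intensity | threshold offset above the local mean |
| `grain_size_T` | 100 | px² | minimum area (strict >) of a large-vessel component |
| `max_vessel_width` | 18 | px | maximum span of a gradient extremum pair |
| `line_length_l` | 15 | px | oriented line-detector length |
| `n_orientations` | 8 | – | detector orientations (22.5° spacing) |
| `svm_sigma` | auto | – | RBF width; median pairwise distance of scaled training rows |
| `svm_C1`, `svm_C2` | 1, 10 | – | class costs (vessel, noise) |
| `prune_cap` | 1000 | px | classified-positive cap per image |
| `hessian_sigma` | 1.5 | px | Gaussian-derivative scale of the Hessian |
| `lambda1_min`, `lambda2_max` | auto | – | growth gates (see below) |
| `step`, `max_steps` | 1, 200 | px, – | growth step length and budget |
| `direction_weight` | 0.5 | – | D1 weight in the growth direction blend |

All intensities live on the [0, 1] scale from the moment an image is
read, which removes any bit-depth dependence.  Coordinates are (row,
col), 1-based in R, row 1 at the top.  A missing FOV mask means
"everything inside".

Two defaults deserve their rationale.  `thresh_window` is 25 rather than
the smaller windows often quoted for local-mean thresholds: the window
must comfortably exceed twice the widest vessel (up to 12 px here),
otherwise the local mean inside a wide vessel is dominated by the vessel
itself and its interior never passes.  `max_vessel_width` is 18 because a
horizontal or vertical profile crosses a diagonally running vessel of
width w over up to √2·w ≈ 17 pixels; a cap of 15 would reject legitimate
extremum pairs on wide diagonal vessels.

## The growth gates

λ1min and λ2max default to *segment-adaptive* values: λ1min is 15 % of
the 99th percentile of λ1 over the classified segment pixels, and λ2max
is 2·λ1min.  Tying the gates to the segments' own eigenvalue
distribution makes them contrast-scale free (the same code tracks a
high- or low-contrast image).  The fractions are deliberately
permissive: the classified segments are the *strongest* thin-vessel
fragments, while growth exists precisely to follow the fainter
continuation of those vessels; a gate calibrated tightly to the segments
would stop at the first faint gap.  The λ1 floor still rejects flat
background, which is what terminates every path.

Two numerical details matter on one-to-two-pixel-wide ridges.  First,
each candidate point is re-centered: it is shifted along the
across-vessel eigenvector (offsets 0, ±0.5, ±1 px) to the position of
maximal interpolated λ1 before the gate is tested.  Without this, the
discrete step drifts off the crest and the gate fails spuriously after a
few steps.  Second, accepted points are rasterized with their local
cross-section — the two neighbors one pixel across the vessel are
included when they pass the gate themselves — so a grown path covers the
vessel's width rather than a one-pixel trace.

## Interpretation choices

Several parts of the procedure admit more than one reading; the package
settles them as follows.

* **Threshold rule.**  "Adaptive local threshold" is implemented as
  local-mean-plus-offset.  The offset default passes 12–15 % of FOV
  pixels on the bundled phantoms, bracketing the 12.3–12.7 % of pixels
  human experts mark as vessel.
* **Extremum pairing.**  A profile extremum is a point strictly greater
  (or smaller) than both neighbors on the gradient profile smoothed with
  σ = 2 along the scan direction.  The smoothing scale is the smallest
  that suppresses noise extrema on the near-flat gradient plateau inside
  wide vessels, which otherwise break the min→max pairing.  Only
  minimum-then-maximum pairs are marked: that is the signature of a
  *dark* bar; bright structures (the disc rim crossed tangentially) give
  the opposite order and are never filled.
* **Run qualification.**  A marked run is kept when it shares a pixel
  with a candidate on that same profile.  This fills interior holes of a
  partially detected vessel and guarantees that no refined pixel lies
  farther than `max_vessel_width` from a candidate.
* **D1/D2 selection.**  Both are chosen by the line *mean* only (minimum
  and maximum respectively, ties to the lower orientation index), and the
  directions found on the gray image are reused on the wavelet and
  curvelet moduli.  Difference features are absolute values, so they are
  nonnegative by construction.
* **Wavelet/curvelet moduli.**  The Haar level is undecimated (à trous),
  with the modulus √(Wh² + Wv²) over the horizontal and vertical detail
  bands only.  The curvelet stage is an FFT-domain wedge filter bank:
  one coarse radial band plus eight overlapping angular wedges (periodic
  Hann windows over 180°) on the detail band, forming an exact partition
  of unity — the coarse reconstruction plus the eight per-wedge
  reconstructions reproduce the input to machine precision.  The modulus
  is the root-sum-square of the eight wedge reconstructions.  Both
  transforms run on the *original* gray image, not the normalized one.
* **The 1000-pixel rule.**  "Classify until fewer than 1000 pixels
  remain" is realized as decision-threshold tightening on the SVM scores
  (keep the cap highest-scoring pixels, ties kept together), applied per
  image.  Re-training the classifier on its own predictions would be
  ill-posed; score ranking reproduces the intended behavior exactly.
* **Endpoints.**  An endpoint is a segment pixel with exactly one
  8-neighbor in the segment; isolated pixels yield two endpoint records
  with opposite directions.  The outgoing direction is the local D1
  direction, signed away from the segment body.  `find_endpoints` takes
  the gray image and detector bank as arguments because D1 is an image
  property, not a mask property.
* **SVM determinism.**  The quadratic-program solver is run to a
  convergence tolerance of 1e-9, which makes the fitted decision
  function independent of training-row order to ~1e-9 — tight enough
  that repeated pipeline runs reproduce masks bit for bit.

## What the phantom generator emulates

`generate_phantom()` builds a 192 × 192 image with a circular FOV, a
radially falling background, a bright Gaussian optic-disc blob, and
vessels as curvature-bounded random-walk polylines rooted at the disc:
by default two large vessels (widths stratified over 4–12 px, narrowing
and fading distally) and eight thin vessels (widths 1–3 px) branching
off them.  Thin branches start just past their parent's edge with a
deliberately faint junction and a contrast profile that decays from
about 0.13 to 0.026 on the [0, 1] scale — above the threshold floor at
the root, below it at the tail — so the binary image catches only
fragments of them, each far below the grain size *T*.  That is the
regime the classifier and the tracking stage exist for.  Gaussian noise
(σ = 0.015 on the green channel, doubled on red and blue) and a slight
cross-profile blur (σ = 0.5) finish the image.  Ground truth is exact:
disjoint large and thin masks whose union covers 8–16 % of the FOV
(thin: 1–8 %), bracketing expert-marked vessel loads.

The phantoms deliberately do **not** emulate pathologies (exudates,
microaneurysms, hemorrhages), vessel crossings of independent trees,
central light reflexes inside large vessels, or JPEG-like acquisition
artifacts.  Passing the bundled suites therefore demonstrates that the
pipeline recovers curvilinear dark structures under radial illumination
and noise — not that it is robust to pathology; on real data the
classifier should be retrained on residual images with manual ground
truth via the same `sample_training_set()` route.

## Problem sizes and runtime

The default test and acceptance workload is the 20-phantom suite at
192 × 192 (a size at which every stage keeps its DRIVE-scale parameter
ratios for thin vessels while one full train-and-segment pass stays
around a minute), 100 training pixels per image (2000 rows, balanced
1000/1000), and the oracle-equivalence checks run on ≥ 100 random small
instances per primitive.

## Known limitations

* The 25 × 25 median background is unreliable where a ≥ 12 px vessel
  crosses the window diagonally (the vessel then occupies more than half
  the window); the extremum-pair refinement compensates, but the binary
  map alone under-covers the widest vessels.
* Large-vessel masks inflate by a pixel or two around true vessel
  boundaries — the price of filling runs between gradient extrema, which
  sit at the blurred edge inflection points.  Accuracy on the phantom
  suite absorbs this; on low-resolution images the inflation is
  proportionally larger.
* Growth follows a single path per endpoint: a branch point inside a
  grown stretch is only explored if the classifier found a fragment on
  the branch.
* The optic-disc model is localization only; images whose brightest
  region is pathology (large exudates) would mislead the disc-edge
  erasure.
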