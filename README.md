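# retiseg

Segmentation of blood vessels in retinal fundus photographs, for
researchers working on retinal image analysis and for anyone who needs
vessel masks as input to downstream morphometry (caliber, tortuosity,
branching).  Retinal vessels split into two contrast regimes — large
vessels with good contrast, thin vessels barely above the noise floor —
and `retiseg` treats them with a hybrid pipeline:

1. **Large vessels**: the green channel *g* is normalized against a
   25 × 25 median-filtered background *b* (so vessels become bright in
   *n = b − g*), thresholded where *n* exceeds its local mean by an
   offset, and filtered to 8-connected components with area > *T* = 100.
   Optic-disc rim edges are erased and vessel interiors filled using the
   signature of a dark bar on a gradient profile: a local minimum
   followed by a local maximum within the maximum vessel width
   (one-sided disc edges have a single extremum and fail the test).
2. **Thin-vessel fragments**: each residual binary pixel gets a
   12-dimensional feature vector from 8 oriented line detectors (22.5°
   apart, length *l* = 15) applied to the gray image and to two edge
   moduli — undecimated Haar wavelet, M_W = √(W_h² + W_v²), and a
   curvelet-style directional modulus M_C = √(Σᵢ Cᵢ²) over eight angular
   wedge reconstructions:
   [M_g1, SD_g1, D_m_g, D_sd_g, M_W1, SD_W1, D_m_W, D_sd_W, M_C1, SD_C1,
   D_m_C, D_sd_C], where the "1" statistics follow the best-aligned
   (minimum-mean) direction D1 and the D terms are |D2 − D1| differences.
   After min–max scaling to [−1, 1] (x = 2(x − x_min)/(x_max − x_min) − 1),
   an RBF-SVM, K(a,b) = exp(−‖a−b‖²/2σ²), with asymmetric class costs
   (C1 = 1 for vessel, C2 = 10 for noise) classifies the fragments, and
   the decision threshold is tightened until at most 1000 pixels per
   image remain.
3. **Tracking growth**: classified segments grow from their endpoints
   along a blend of D1 and the Hessian ridge direction, while the
   Gaussian-derivative Hessian eigenvalues (λ1 ≥ λ2) certify a dark
   vessel: λ1 ≫ 0 across, λ2 ≈ 0 along.  The final mask is
   large ∪ tracked-thin; sensitivity, specificity and accuracy are
   computed inside the field of view (FOV).

A synthetic fundus phantom generator with exact per-pixel ground truth
makes every stage testable without downloading image databases; the
DRIVE directory layout is supported as an optional input
(`load_drive_case()`).

## Worked example

```r
library(retiseg)

suite <- make_fixture_suite(seed = 42, n_images = 20)   # synthetic fundus suite
suite[[1]]
#> <phantom seed 1228985497: 192 x 192, vessel fraction 9.0% (thin 2.2%)>

model <- train_vessel_classifier(suite, pipeline_config())
model
#> <svm_vessel_model: RBF sigma=1.125, C1=1, C2=10, 501 support vectors>

res <- segment_vessels(suite[[1]]$image, model)
res
#> <vessel_segmentation: 10.5% of FOV vessel (2428 large px, 358 thin px, 140 thin-segment px)>

compute_metrics(res$mask, suite[[1]]$truth, suite[[1]]$fov)
#> <seg_metrics: sens 0.9429, spec 0.9782, acc 0.9750 (tp 2179, fp 507, tn 22782, fn 132)>
```

The phantom line says image 1 carries a 9 % vessel load of its FOV, 2.2
percentage points of it thin (1–3 px) vessels.  The model line reports
the fitted kernel width (median-heuristic σ on the scaled features) and
the asymmetric costs.  The segmentation line breaks the final mask into
large-vessel pixels, classified thin-segment pixels (140, under the
1000-pixel cap) and thin pixels after tracking growth (358 — growth more
than doubled the thin coverage).  The metrics line is the pixel-level
confusion over the FOV against exact phantom truth: 94.3 % of vessel
pixels recovered at 97.5 % overall accuracy.

`plot(res)` overlays the mask on the green channel.  A command-line
front end with the same stages lives at `inst/cli/retiseg.R`
(`synth`, `preprocess`, `large-vessels`, `train`, `segment`, `track`,
`evaluate`).

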