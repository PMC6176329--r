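# spinecurve

Unsupervised recognition of spinal-curvature abnormalities (scoliosis,
kyphosis, lordosis) in 2-D grayscale spine images, for researchers who need
a fully automatic curvature measurement without per-image manual labelling.

The pipeline joins three classical components end to end:

1. **Vertebra detection** — a cascade gentle-AdaBoost classifier over fused
   Haar-like + LBP + HOG descriptors, scanned over the image in raster
   order. Boosting weights start at `1/(2m)` per negative and `1/(2l)` per
   positive; each round picks the decision stump minimising the weighted
   error `ε = Σᵢ wᵢ|h(xᵢ) − yᵢ|`, updates `w ← w·β^(1−e)` with
   `β = ε/(1−ε)`, and the stage accepts a window when
   `Σₜ αₜ hₜ(x) ≥ θ` with `αₜ = log(1/βₜ)` and `θ` lowered from the
   majority vote `½Σαₜ` to hit a per-stage true-positive-rate target
   (0.9) at a false-positive-rate target (0.03).
2. **Vertebra segmentation** — distance-regularized level-set evolution
   (DRLSE) seeded by each detected box:
   `∂φ/∂t = μ div(d_p(|∇φ|)∇φ) + λ δ_ε(φ) div(g∇φ/|∇φ|) + α g δ_ε(φ)`,
   with edge indicator `g = 1/(1+|∇(G_σ∗I)|²)`, the double-well potential
   behind `d_p`, and defaults μ=0.04, λ=5, α=1.5, ε=1.5, 200 iterations.
3. **Curvature measurement and diagnosis** — mask centroids
   (`k = Σx·I/ΣI`, `l = Σy·I/ΣI`), a least-squares polynomial spinal curve
   `col = f(row)`, the tangent angle between the terminal centroids
   `φ = |arctan f′(b) − arctan f′(a)|`, and medical-prior rules: coronal
   `φ ≥ 10°` ⇒ scoliosis; sagittal normal ranges cervical [35°, 45°],
   thoracic [20°, 45°], lumbar [40°, 60°].

A synthetic spine-phantom generator (bright vertebra-like blobs along an
analytic centerline, with exact ground-truth centroids, boxes and tangent
angle) makes every stage testable on a desk machine; see the methods
vignette (`vignettes/spinecurve-methods.Rmd`) for the model, parameter and
numerical choices.

## Worked example

Train a small detector on phantom patches, then run the whole chain on a
held-out phantom with a built-in 30° curvature:

```r
library(spinecurve)

# a synthetic spine with a known 30-degree tangent angle
spec <- phantomSpecForAngle(30, seed = 7)
phantom <- generateSpinePhantom(spec)
phiTrue(phantom$truth)
#> [1] 30

# train a phantom detector (24 x 30 window, 3 configured stages)
win <- c(24L, 30L)
patches <- lapply(c(101, 102, 103), function(s)
  generateTrainingPatches(phantomSpecForAngle(c(0, 15, 35)[s - 100], seed = s),
                          nPos = 60, nNeg = 120, window = win))
pos <- array(unlist(lapply(patches, function(p) p$patches[, , p$labels == 1])),
             dim = c(win, 180))
neg <- array(unlist(lapply(patches, function(p) p$patches[, , p$labels == 0])),
             dim = c(win, 360))
model <- trainCascade(pos, neg, featureConfig(window = win),
                      cascadeConfig(nStages = 3, minWeakPerStage = 6))
#> cascade: no false positives remain; stopping at stage 1
model
#> CascadeModel: 1 stage(s), window 24x30, 4532 features
#>   stage TPR/FPR on training data:
#>    1: TPR 1.000  FPR 0.000  (6 learners)

# detect -> segment -> measure -> diagnose
det <- detectVertebrae(model, phantom$image, scanConfig(stride = 4L, nScales = 1L))
head(det, 3)
#>   number top left height width    score
#> 1      1   3   40     24    30 124.6285
#> 2      2  42   40     24    30 126.6453
#> 3      3  82   46     24    30 125.7456
masks <- segmentVertebrae(phantom$image, det, clahe = FALSE)
analyzeSpine(masks, view = "coronal")
#> CurvatureReport (coronal): phi = 29.75 deg -> ABNORMAL
#>   rule: scoliosis if phi >= 10 deg (coronal); phi = 29.75
#>   curve fit: R^2 = 1.0000, RMSE = 0.1100 (8 centroids)
detectionRecall(det, phantom$truth, iouMin = 0.5)
#> [1] 1
```

The report reads: the recovered tangent angle is 29.75° against the
phantom's true 30°; since the view is coronal and 29.75 ≥ 10, the rule
fires and the spine is labelled abnormal (scoliosis). The curve fit is
essentially exact (R² ≈ 1, RMSE 0.11 px of lateral deviation), and every
ground-truth vertebra was matched by a detection at IoU ≥ 0.5.

On clinical-style images use `pipelineConfig()` defaults (90 × 80 window,
stride 8, image pyramid, CLAHE on) and `runSpinePipeline(image, model,
view, region)`, which writes the detections CSV, per-vertebra mask PNGs,
centroids CSV and a YAML report. A command-line front end with
`simulate` / `train-detector` / `detect` / `segment` / `analyze` / `run`
subcommands lives at `inst/scripts/spinecurve.R`.

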