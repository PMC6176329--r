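Package: spinecurve
Title: Vertebra Detection, Level-Set Segmentation and Spinal Curvature
    Measurement in 2-D Spine Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An unsupervised pipeline for recognising scoliosis and other
    spinal-curvature abnormalities in 2-D grayscale spine images. Vertebral
    bodies are detected by a cascade gentle-AdaBoost classifier over fused
    Haar-like, local-binary-pattern and histogram-of-oriented-gradient
    descriptors; each detected bounding box seeds a distance-regularized
    level-set evolution that segments the vertebral body; segmented masks
    yield vertebral centroids, a least-squares spinal curve, the tangent-angle
    spinal curvature, and a rule-based normal/abnormal diagnosis from medical
    prior knowledge. A synthetic spine-phantom generator with analytic ground
    truth makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'spinecurve-package.R'
    'AllGenerics.R'
    'utils.R'
    'AllClasses.R'
    'RcppExports.R'
    'features.R'
    'cascade.R'
    'config.R'
    'drlse.R'
    'io.R'
    'phantom.R'
    'pipeline.R'
    'spine.R'
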