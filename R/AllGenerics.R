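#' @include spinecurve-package.R
NULL

#' Pixel matrix of an image object
#'
#' @param x an object holding image data.
#' @return A numeric matrix (rows x cols) of intensities in `[0, 1]`.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' View label (coronal / sagittal / unknown) of an image object
#' @param x an object with a view label.
#' @return A character scalar.
#' @export
setGeneric("imageView", function(x) standardGeneric("imageView"))

#' Pixel spacing in millimetres per pixel
#' @param x an object carrying pixel spacing.
#' @return A numeric scalar (mm/px).
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' Ground-truth or extracted vertebral centroids
#' @param x an object holding centroids.
#' @return A numeric matrix with columns `row`, `col` (sub-pixel, 1-based).
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' Ground-truth vertebra bounding boxes
#' @param x an object holding boxes.
#' @return An integer matrix with columns `top`, `left`, `height`, `width`
#'   (1-based, closed; a box covers rows `top..top+height-1`).
#' @export
setGeneric("truthBoxes", function(x) standardGeneric("truthBoxes"))

#' Analytic tangent angle of a phantom centerline, in degrees
#' @param x a phantom ground-truth object.
#' @return Non-negative numeric scalar (degrees).
#' @export
setGeneric("phiTrue", function(x) standardGeneric("phiTrue"))

#' Detection window geometry of a cascade model
#' @param x a cascade model.
#' @return Integer vector `c(rows, cols)`.
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' Number of trained stages in a cascade model
#' @param x a cascade model.
#' @return Integer scalar.
#' @export
setGeneric("nStages", function(x) standardGeneric("nStages"))

#' Per-stage training report of a cascade model
#' @param x a cascade model.
#' @return A data.frame with one row per stage (TPR, FPR, learners).
#' @export
setGeneric("trainingReport", function(x) standardGeneric("trainingReport"))

#' Spinal curvature angle of a fitted curve or report, in degrees
#' @param x a fitted spinal curve or a curvature report.
#' @return Non-negative numeric scalar (degrees).
#' @export
setGeneric("curvatureAngle", function(x) standardGeneric("curvatureAngle"))

#' Diagnosis label of a curvature report
#' @param x a curvature report.
#' @return `"normal"` or `"abnormal"`.
#' @export
setGeneric("diagnosis", function(x) standardGeneric("diagnosis"))
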