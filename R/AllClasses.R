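#' @include utils.R
NULL

#' SpineImage: a 2-D grayscale spine slice
#'
#' The pipeline's raw input: an intensity matrix in `[0, 1]` (rows x cols,
#' cranio-caudal axis along rows), a view label, and the pixel spacing in
#' millimetres per pixel.
#'
#' @slot pixels numeric matrix of intensities in `[0, 1]`.
#' @slot view `"coronal"`, `"sagittal"` or `"unknown"`.
#' @slot spacing pixel spacing in mm/px (isotropic).
#' @seealso [SpineImage()], [readImagePlane()]
#' @export
setClass("SpineImage",
  representation(pixels = "matrix", view = "character", spacing = "numeric"),
  prototype(view = "unknown", spacing = 1))

setValidity("SpineImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (anyNA(p) || any(!is.finite(p))) return("pixel intensities must be finite")
  if (min(p) < 0 || max(p) > 1) return("pixel intensities must lie in [0, 1]")
  if (!object@view %in% c("coronal", "sagittal", "unknown"))
    return("view must be 'coronal', 'sagittal' or 'unknown'")
  if (length(object@spacing) != 1 || object@spacing <= 0)
    return("spacing must be a positive scalar (mm/px)")
  TRUE
})

#' Construct a SpineImage
#'
#' @param pixels numeric matrix of intensities in `[0, 1]`.
#' @param view view label: `"coronal"`, `"sagittal"` or `"unknown"`.
#' @param spacing pixel spacing in mm/px; default 1.
#' @return A [SpineImage-class] object.
#' @examples
#' img <- SpineImage(matrix(runif(200), 20, 10), view = "coronal")
#' dim(pixels(img))
#' @export
SpineImage <- function(pixels, view = "unknown", spacing = 1) {
  new("SpineImage", pixels = pixels, view = view, spacing = spacing)
}

#' @describeIn SpineImage-class intensity matrix accessor
#' @param x a `SpineImage`.
#' @export
setMethod("pixels", "SpineImage", function(x) x@pixels)

#' @describeIn SpineImage-class view label accessor
#' @export
setMethod("imageView", "SpineImage", function(x) x@view)

#' @describeIn SpineImage-class pixel-spacing accessor (mm/px)
#' @export
setMethod("pixelSpacing", "SpineImage", function(x) x@spacing)

setMethod("show", "SpineImage", function(object) {
  cat(sprintf("SpineImage: %d x %d px, view = %s, spacing = %g mm/px\n",
              nrow(object@pixels), ncol(object@pixels),
              object@view, object@spacing))
})

#' PhantomSpec: parameters of a synthetic spine phantom
#'
#' Describes a synthetic spine: vertebra-like bright blobs (superellipses)
#' placed at equal arc-length spacing along an analytic polynomial
#' centerline on a darker noisy background.
#'
#' @slot nVertebrae number of vertebrae (>= 2).
#' @slot centerlineCoeffs polynomial coefficients (increasing order) of the
#'   lateral offset `col = f(row)`.
#' @slot vertebraSize `c(height, width)` of each blob in px.
#' @slot spacingPx arc-length spacing between consecutive centers, px.
#' @slot fgIntensity,bgIntensity foreground/background gray levels in `[0,1]`.
#' @slot noiseSd additive Gaussian noise standard deviation.
#' @slot imageShape `c(rows, cols)` of the phantom image.
#' @slot seed integer random seed; fixes the noise realisation.
#' @seealso [PhantomSpec()], [generateSpinePhantom()]
#' @export
setClass("PhantomSpec",
  representation(nVertebrae = "integer", centerlineCoeffs = "numeric",
                 vertebraSize = "integer", spacingPx = "numeric",
                 fgIntensity = "numeric", bgIntensity = "numeric",
                 noiseSd = "numeric", imageShape = "integer", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@nVertebrae < 2L) return("nVertebrae must be >= 2")
  if (object@fgIntensity <= object@bgIntensity)
    return("fgIntensity must exceed bgIntensity")
  if (any(c(object@fgIntensity, object@bgIntensity) < 0) ||
      any(c(object@fgIntensity, object@bgIntensity) > 1))
    return("intensities must lie in [0, 1]")
  if (length(object@vertebraSize) != 2 || any(object@vertebraSize < 3))
    return("vertebraSize must be c(height, width), each >= 3 px")
  if (object@spacingPx <= max(object@vertebraSize))
    return("spacingPx must exceed the vertebra size (blobs must not overlap)")
  if (length(object@imageShape) != 2 || any(object@imageShape < 10))
    return("imageShape must be c(rows, cols), each >= 10")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Construct a PhantomSpec
#'
#' @param nVertebrae number of vertebrae (>= 2).
#' @param centerlineCoeffs polynomial coefficients, increasing order, of the
#'   lateral centerline `col = f(row)`.
#' @param vertebraSize blob `c(height, width)` in px.
#' @param spacingPx arc-length spacing between consecutive blob centers (px);
#'   must exceed the blob size.
#' @param fgIntensity,bgIntensity foreground/background gray levels.
#' @param noiseSd additive Gaussian noise sd (clipped to `[0,1]` after adding).
#' @param imageShape image `c(rows, cols)`.
#' @param seed integer seed for the noise realisation.
#' @return A [PhantomSpec-class] object.
#' @export
PhantomSpec <- function(nVertebrae = 8, centerlineCoeffs = c(60, 0, 0),
                        vertebraSize = c(20, 26), spacingPx = 40,
                        fgIntensity = 0.85, bgIntensity = 0.25,
                        noiseSd = 0.04, imageShape = c(420, 260),
                        seed = 1) {
  new("PhantomSpec", nVertebrae = as.integer(nVertebrae),
      centerlineCoeffs = as.numeric(centerlineCoeffs),
      vertebraSize = as.integer(vertebraSize), spacingPx = as.numeric(spacingPx),
      fgIntensity = fgIntensity, bgIntensity = bgIntensity,
      noiseSd = noiseSd, imageShape = as.integer(imageShape),
      seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %d vertebrae (%dx%d px, spacing %g px) on a ",
                     "%dx%d image\n  centerline coeffs: %s; fg/bg %g/%g; ",
                     "noise sd %g; seed %d\n"),
              object@nVertebrae, object@vertebraSize[1], object@vertebraSize[2],
              object@spacingPx, object@imageShape[1], object@imageShape[2],
              paste(signif(object@centerlineCoeffs, 4), collapse = ", "),
              object@fgIntensity, object@bgIntensity, object@noiseSd,
              object@seed))
})

#' PhantomTruth: ground truth of a synthetic spine phantom
#'
#' @slot centroids numeric matrix (`row`, `col`), one row per vertebra,
#'   ordered superior to inferior; sub-pixel.
#' @slot boxes integer matrix (`top`, `left`, `height`, `width`), one row per
#'   vertebra.
#' @slot phiTrue analytic tangent angle (degrees, >= 0) of the centerline
#'   between the first and last centroid.
#' @export
setClass("PhantomTruth",
  representation(centroids = "matrix", boxes = "matrix", phiTrue = "numeric"))

setValidity("PhantomTruth", function(object) {
  if (nrow(object@centroids) != nrow(object@boxes))
    return("centroids and boxes must have one row per vertebra")
  if (object@phiTrue < 0) return("phiTrue must be >= 0")
  TRUE
})

#' @describeIn PhantomTruth-class centroid matrix accessor
#' @param x a `PhantomTruth`.
#' @export
setMethod("centroids", "PhantomTruth", function(x) x@centroids)

#' @describeIn PhantomTruth-class bounding-box matrix accessor
#' @export
setMethod("truthBoxes", "PhantomTruth", function(x) x@boxes)

#' @describeIn PhantomTruth-class analytic tangent angle (degrees)
#' @export
setMethod("phiTrue", "PhantomTruth", function(x) x@phiTrue)

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %d vertebrae, phiTrue = %.3f deg\n",
              nrow(object@centroids), object@phiTrue))
})

#' CascadeModel: a trained cascade gentle-AdaBoost vertebra detector
#'
#' An ordered list of boosted stage classifiers (each a weighted set of
#' decision stumps with an adjusted acceptance threshold), the descriptor
#' configuration, per-feature z-score normalization statistics learned on the
#' training set, and the canonical window geometry. A window is accepted iff
#' every stage accepts it.
#'
#' @slot window integer `c(rows, cols)` of the canonical detection window.
#' @slot featureConfig descriptor configuration, see [featureConfig()].
#' @slot normCenter,normScale per-feature standardization statistics.
#' @slot stages list of stage classifiers (stumps, alphas, threshold).
#' @slot report per-stage training TPR/FPR data.frame.
#' @slot version serialization format version.
#' @export
setClass("CascadeModel",
  representation(window = "integer", featureConfig = "list",
                 normCenter = "numeric", normScale = "numeric",
                 stages = "list", report = "data.frame", version = "character"),
  prototype(version = "1.0"))

setValidity("CascadeModel", function(object) {
  if (length(object@window) != 2 || any(object@window < 8))
    return("window must be c(rows, cols), each >= 8")
  if (length(object@normCenter) != length(object@normScale))
    return("normalization center/scale lengths differ")
  if (any(object@normScale <= 0)) return("normScale entries must be positive")
  TRUE
})

#' @describeIn CascadeModel-class window geometry `c(rows, cols)`
#' @param x a `CascadeModel`.
#' @export
setMethod("windowSize", "CascadeModel", function(x) x@window)

#' @describeIn CascadeModel-class number of trained stages
#' @export
setMethod("nStages", "CascadeModel", function(x) length(x@stages))

#' @describeIn CascadeModel-class per-stage training report
#' @export
setMethod("trainingReport", "CascadeModel", function(x) x@report)

setMethod("show", "CascadeModel", function(object) {
  cat(sprintf("CascadeModel: %d stage(s), window %dx%d, %d features\n",
              length(object@stages), object@window[1], object@window[2],
              length(object@normCenter)))
  if (nrow(object@report) > 0) {
    cat("  stage TPR/FPR on training data:\n")
    for (i in seq_len(nrow(object@report)))
      cat(sprintf("   %2d: TPR %.3f  FPR %.3f  (%d learners)\n", i,
                  object@report$tpr[i], object@report$fpr[i],
                  object@report$learners[i]))
  }
})

#' VertebraMask: a per-vertebra binary segmentation
#'
#' A 0/1 mask on a region-of-interest grid, the ROI's offset in the source
#' image, and the provenance detection number.
#'
#' @slot mask integer/numeric matrix of 0/1 values; 1 = vertebra.
#' @slot offset integer `c(top, left)` of the ROI in the full image (1-based).
#' @slot number provenance detection number.
#' @export
setClass("VertebraMask",
  representation(mask = "matrix", offset = "integer", number = "integer"))

setValidity("VertebraMask", function(object) {
  if (!all(object@mask %in% c(0, 1))) return("mask values must be 0/1")
  if (length(object@offset) != 2 || any(object@offset < 1))
    return("offset must be c(top, left), 1-based")
  TRUE
})

#' Construct a VertebraMask
#' @param mask 0/1 matrix (1 = vertebra).
#' @param offset `c(top, left)` of the mask grid in the full image, 1-based.
#' @param number provenance detection number.
#' @return A [VertebraMask-class] object.
#' @export
VertebraMask <- function(mask, offset = c(1L, 1L), number = 1L) {
  new("VertebraMask", mask = mask, offset = as.integer(offset),
      number = as.integer(number))
}

setMethod("show", "VertebraMask", function(object) {
  cat(sprintf("VertebraMask #%d: %dx%d ROI at (%d,%d), %d foreground px\n",
              object@number, nrow(object@mask), ncol(object@mask),
              object@offset[1], object@offset[2], sum(object@mask)))
})

#' SpineCurve: a least-squares polynomial spinal curve
#'
#' The lateral coordinate fitted as a polynomial of the cranio-caudal
#' coordinate, `col = f(row)`, with the fit domain spanning the two terminal
#' centroids and Eq-of-fit quality statistics (coefficient of determination
#' and root-mean-squared error).
#'
#' @slot coefficients polynomial coefficients, increasing order.
#' @slot degree polynomial degree.
#' @slot domain `c(a, b)`: cranio-caudal coordinates of the terminal centroids.
#' @slot rSquared coefficient of determination of the fit.
#' @slot rmse root-mean-squared error of the fit.
#' @slot nPoints number of centroids fitted.
#' @export
setClass("SpineCurve",
  representation(coefficients = "numeric", degree = "integer",
                 domain = "numeric", rSquared = "numeric", rmse = "numeric",
                 nPoints = "integer"))

setValidity("SpineCurve", function(object) {
  if (object@degree + 1L > object@nPoints)
    return("degree + 1 must not exceed the number of fitted centroids")
  if (length(object@domain) != 2) return("domain must be c(a, b)")
  TRUE
})

#' @describeIn SpineCurve-class tangent angle between terminal tangents, deg
#' @param x a `SpineCurve`.
#' @export
setMethod("curvatureAngle", "SpineCurve", function(x) {
  dcoef <- polyDeriv(x@coefficients)
  abs(atan(polyval(dcoef, x@domain[2])) - atan(polyval(dcoef, x@domain[1]))) *
    180 / pi
})

setMethod("show", "SpineCurve", function(object) {
  cat(sprintf(paste0("SpineCurve: degree %d on [%.2f, %.2f] (%d centroids)\n",
                     "  R^2 = %.4f, RMSE = %.4f, tangent angle = %.3f deg\n"),
              object@degree, object@domain[1], object@domain[2],
              object@nPoints, object@rSquared, object@rmse,
              curvatureAngle(object)))
})

#' CurvatureReport: curvature angle, fit quality and diagnosis
#'
#' @slot phi curvature angle in degrees (>= 0).
#' @slot view `"coronal"` or `"sagittal"`.
#' @slot region `"cervical"`, `"thoracic"`, `"lumbar"` or `"whole"`.
#' @slot diagnosisLabel `"normal"` or `"abnormal"`.
#' @slot rule the medical-prior rule that fired.
#' @slot rSquared,rmse spinal-curve fit quality (NA when not applicable).
#' @slot nCentroids number of centroids behind the fit.
#' @export
setClass("CurvatureReport",
  representation(phi = "numeric", view = "character", region = "character",
                 diagnosisLabel = "character", rule = "character",
                 rSquared = "numeric", rmse = "numeric",
                 nCentroids = "integer"),
  prototype(rSquared = NA_real_, rmse = NA_real_, nCentroids = NA_integer_))

setValidity("CurvatureReport", function(object) {
  if (object@phi < 0) return("phi must be >= 0 degrees")
  if (!object@view %in% c("coronal", "sagittal"))
    return("view must be 'coronal' or 'sagittal'")
  if (!object@diagnosisLabel %in% c("normal", "abnormal"))
    return("diagnosis must be 'normal' or 'abnormal'")
  TRUE
})

#' @describeIn CurvatureReport-class curvature angle (degrees)
#' @param x a `CurvatureReport`.
#' @export
setMethod("curvatureAngle", "CurvatureReport", function(x) x@phi)

#' @describeIn CurvatureReport-class diagnosis label
#' @export
setMethod("diagnosis", "CurvatureReport", function(x) x@diagnosisLabel)

#' @describeIn CurvatureReport-class view label
#' @export
setMethod("imageView", "CurvatureReport", function(x) x@view)

setMethod("show", "CurvatureReport", function(object) {
  cat(sprintf("CurvatureReport (%s%s): phi = %.2f deg -> %s\n  rule: %s\n",
              object@view,
              if (object@region == "whole") "" else paste0(" ", object@region),
              object@phi, toupper(object@diagnosisLabel), object@rule))
  if (!is.na(object@rSquared))
    cat(sprintf("  curve fit: R^2 = %.4f, RMSE = %.4f (%d centroids)\n",
                object@rSquared, object@rmse, object@nCentroids))
})
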