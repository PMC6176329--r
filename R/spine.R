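#' @include AllClasses.R
NULL

#' Centroid of a binary mask
#'
#' Intensity-mask centre of mass: `k = sum(x I(x,y)) / sum(I)` over rows and
#' `l = sum(y I(x,y)) / sum(I)` over cols. For a [VertebraMask-class] the
#' ROI offset is applied so the centroid is in full-image coordinates.
#'
#' @param mask a 0/1 matrix or a [VertebraMask-class].
#' @return Named numeric `c(row, col)`, sub-pixel, 1-based.
#' @examples
#' m <- matrix(0, 10, 10); m[2:5, 3:8] <- 1
#' extractCentroid(m)  # (3.5, 5.5)
#' @export
extractCentroid <- function(mask) {
  off <- c(0, 0)
  if (is(mask, "VertebraMask")) {
    off <- mask@offset - 1L
    mask <- mask@mask
  }
  tot <- sum(mask)
  if (tot == 0) stop("empty mask: no foreground pixels")
  c(row = sum(row(mask) * mask) / tot + off[1],
    col = sum(col(mask) * mask) / tot + off[2])
}

#' Goodness-of-fit statistics of a curve fit
#'
#' Coefficient of determination `R^2 = 1 - sum((v' - v)^2) / sum((v - vbar)^2)`
#' and root-mean-squared error `RMSE = sqrt(mean((v - v')^2))`, where `v` are
#' the observed and `v'` the fitted values. When the observed values are
#' constant and fitted exactly, `R^2` is reported as 1.
#'
#' @param v observed values.
#' @param vfit fitted values.
#' @return A list with `rSquared` and `rmse`.
#' @export
fitQuality <- function(v, vfit) {
  sse <- sum((vfit - v)^2)
  sst <- sum((v - mean(v))^2)
  r2 <- if (sst == 0) as.numeric(sse < 1e-12) else 1 - sse / sst
  list(rSquared = r2, rmse = sqrt(sse / length(v)))
}

# Degree rule when the user does not override: 3 for >= 5 centroids,
# 2 for 3-4, 1 for 2.
defaultDegree <- function(n) if (n >= 5) 3L else if (n >= 3) 2L else 1L

#' Fit the spinal curve through vertebral centroids
#'
#' Ordinary least-squares polynomial of the lateral coordinate (col) as a
#' function of the cranio-caudal coordinate (row). The fit domain `[a, b]`
#' spans the two terminal centroids. Fit quality (`R^2`, RMSE) is computed on
#' the centroids themselves.
#'
#' @param centroids numeric matrix (`row`, `col`), ordered superior to
#'   inferior, at least `degree + 1` rows with distinct row coordinates.
#' @param degree polynomial degree; default 3 for >= 5 centroids, 2 for 3-4,
#'   1 for 2.
#' @return A [SpineCurve-class].
#' @export
fitSpineCurve <- function(centroids, degree = NULL) {
  centroids <- rbind(centroids)
  n <- nrow(centroids)
  if (is.null(degree)) degree <- defaultDegree(n)
  degree <- as.integer(degree)
  if (n < degree + 1)
    stop("need at least degree + 1 = ", degree + 1, " centroids, got ", n)
  x <- centroids[, 1]; y <- centroids[, 2]
  if (anyDuplicated(x))
    stop("duplicate cranio-caudal coordinates; cannot fit col = f(row)")
  V <- outer(x, 0:degree, `^`)
  fit <- lm.fit(V, y)
  q <- fitQuality(y, V %*% fit$coefficients)
  new("SpineCurve", coefficients = as.numeric(fit$coefficients),
      degree = degree, domain = c(x[1], x[n]),
      rSquared = q$rSquared, rmse = q$rmse, nPoints = as.integer(n))
}

#' Curvature of the spinal curve at a point
#'
#' `k = y'' / (1 + y'^2)^(3/2)` from the fitted polynomial's analytic
#' derivatives.
#'
#' @param curve a [SpineCurve-class].
#' @param x cranio-caudal coordinate(s), inside the fit domain.
#' @return Curvature value(s).
#' @export
curvatureAt <- function(curve, x) {
  d1 <- polyDeriv(curve@coefficients)
  d2 <- polyDeriv(d1)
  polyval(d2, x) / (1 + polyval(d1, x)^2)^(3 / 2)
}

#' Tangent angle of the spinal curve by numeric quadrature
#'
#' Integrates `y'' / (1 + y'^2)` over the fit domain and converts to degrees.
#' The antiderivative is `arctan(y')`, so this must agree with
#' [curvatureAngle()]'s closed form `|arctan y'(b) - arctan y'(a)|` to
#' quadrature accuracy; the closed form is the production path and the
#' quadrature serves as a cross-check.
#'
#' @param curve a [SpineCurve-class].
#' @return Absolute angle in degrees.
#' @export
curvatureAngleQuadrature <- function(curve) {
  d1c <- polyDeriv(curve@coefficients)
  d2c <- polyDeriv(d1c)
  f <- function(x) polyval(d2c, x) / (1 + polyval(d1c, x)^2)
  val <- integrate(f, curve@domain[1], curve@domain[2],
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
  abs(val) * 180 / pi
}

.SAGITTAL_RANGES <- list(cervical = c(35, 45), thoracic = c(20, 45),
                         lumbar = c(40, 60))

#' Diagnose a spinal curvature angle against medical prior knowledge
#'
#' Coronal view: the spine is normally straight, so scoliosis is diagnosed
#' when the tangent angle reaches 10 degrees (`phi >= 10`). Sagittal view:
#' the spine is normally S-shaped with region-specific normal curvatures --
#' cervical lordosis 35-45, thoracic kyphosis 20-45, lumbar lordosis 40-60
#' degrees (closed intervals); an angle outside its region's range is
#' abnormal.
#'
#' @param phi curvature angle in degrees (>= 0).
#' @param view `"coronal"` or `"sagittal"`.
#' @param region required for the sagittal view: `"cervical"`, `"thoracic"`
#'   or `"lumbar"`; optional (annotation only) for coronal.
#' @return A [CurvatureReport-class] (fit-quality slots unset).
#' @examples
#' diagnosis(diagnoseCurvature(30.5, "coronal", "lumbar"))   # abnormal
#' diagnosis(diagnoseCurvature(40.4, "sagittal", "lumbar"))  # normal
#' @export
diagnoseCurvature <- function(phi, view, region = NULL) {
  stopifnot(phi >= 0)
  view <- match.arg(view, c("coronal", "sagittal"))
  if (view == "coronal") {
    label <- if (phi >= 10) "abnormal" else "normal"
    rule <- sprintf("scoliosis if phi >= 10 deg (coronal); phi = %.2f", phi)
    region <- if (is.null(region)) "whole" else region
  } else {
    if (is.null(region))
      stop("the sagittal view requires a region (cervical/thoracic/lumbar)")
    region <- match.arg(region, names(.SAGITTAL_RANGES))
    rng <- .SAGITTAL_RANGES[[region]]
    inside <- phi >= rng[1] && phi <= rng[2]
    label <- if (inside) "normal" else "abnormal"
    rule <- sprintf("sagittal %s normal range [%g, %g] deg; phi = %.2f",
                    region, rng[1], rng[2], phi)
  }
  new("CurvatureReport", phi = phi, view = view, region = region,
      diagnosisLabel = label, rule = rule)
}

#' Full curvature analysis of segmented vertebrae
#'
#' Extracts the centroid of every mask, orders them by detection number
#' (superior to inferior; set `flipOrder` for inverted acquisitions), fits
#' the spinal curve, measures the tangent angle between the terminal
#' centroids and applies the diagnosis rules. Fit quality is carried into
#' the report.
#'
#' @param masks a list of [VertebraMask-class] (or 0/1 matrices).
#' @param view `"coronal"` or `"sagittal"`.
#' @param region spine region (required for sagittal).
#' @param degree polynomial degree override, see [fitSpineCurve()].
#' @param flipOrder reverse the centroid ordering.
#' @return A [CurvatureReport-class].
#' @export
analyzeSpine <- function(masks, view, region = NULL, degree = NULL,
                         flipOrder = FALSE) {
  if (length(masks) < 2) stop("need at least 2 vertebra masks")
  nums <- vapply(seq_along(masks), function(i) {
    mk <- masks[[i]]
    if (is(mk, "VertebraMask")) mk@number else i
  }, 0L)
  cent <- t(vapply(masks, function(mk) {
    tryCatch(extractCentroid(mk),
             error = function(e) stop("mask ", if (is(mk, "VertebraMask"))
               mk@number else "?", ": ", conditionMessage(e)))
  }, c(row = 0, col = 0)))
  ord <- order(nums)
  if (flipOrder) ord <- rev(ord)
  curve <- fitSpineCurve(cent[ord, , drop = FALSE], degree)
  phi <- curvatureAngle(curve)
  rep <- diagnoseCurvature(phi, view, region)
  rep@rSquared <- curve@rSquared
  rep@rmse <- curve@rmse
  rep@nCentroids <- curve@nPoints
  validObject(rep)
  rep
}
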