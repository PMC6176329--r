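#' @include AllClasses.R
NULL

# Margin (px) added around the tight blob bounds to form the ground-truth
# bounding box, mimicking boxes that circumscribe the vertebral body.
.BOX_MARGIN <- 2L
# Minimum gap (px) between a blob and the image border.
.EDGE_PAD <- 4L

# Vertebra-center positions along the centerline at equal arc-length spacing.
# Returns a matrix (row, col); deterministic (no RNG involved).
phantomCenters <- function(spec) {
  vh <- spec@vertebraSize[1]
  coeffs <- spec@centerlineCoeffs
  dcoef <- polyDeriv(coeffs)
  r1 <- vh / 2 + .EDGE_PAD
  grid <- seq(r1, spec@imageShape[1], by = 0.05)
  ds <- sqrt(1 + polyval(dcoef, grid)^2) * 0.05
  arc <- c(0, cumsum(ds[-length(ds)]))
  target <- (seq_len(spec@nVertebrae) - 1) * spec@spacingPx
  if (max(arc) < max(target))
    stop("invalid phantom spec: blobs would exit the image bounds (rows)")
  rows <- approx(arc, grid, xout = target)$y
  cbind(row = rows, col = polyval(coeffs, rows))
}

# Rasterize one superellipse blob (exponent 4, a rounded rectangle) of
# `size` = c(h, w) centred at sub-pixel `center` = c(row, col) on an
# nr x nc grid restricted to the rectangle rows0/cols0; returns logical.
blobIndicator <- function(center, size, rows, cols) {
  a <- size[1] / 2; b <- size[2] / 2
  rr <- outer(rows - center[1], rep(1, length(cols)))
  cc <- outer(rep(1, length(rows)), cols - center[2])
  (abs(rr) / a)^4 + (abs(cc) / b)^4 <= 1
}

# Tight ground-truth box around a blob (with the fixed circumscribing margin).
blobBox <- function(center, size) {
  top <- round(center[1] - size[1] / 2) - .BOX_MARGIN
  left <- round(center[2] - size[2] / 2) - .BOX_MARGIN
  c(top = top, left = left,
    height = size[1] + 2L * .BOX_MARGIN, width = size[2] + 2L * .BOX_MARGIN)
}

#' Generate a synthetic spine phantom with ground truth
#'
#' Draws `nVertebrae` bright superellipse blobs (vertebra-like rounded
#' rectangles) at equal arc-length spacing along the spec's polynomial
#' centerline, on a darker background; the image is lightly smoothed and
#' corrupted with additive Gaussian noise clipped to `[0, 1]`. The ground
#' truth holds the analytic sub-pixel blob centers, their bounding boxes, and
#' the closed-form tangent angle of the centerline between the first and last
#' centroid. Bit-identical for a fixed spec (including seed).
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements `image` ([SpineImage-class]) and `truth`
#'   ([PhantomTruth-class]).
#' @examples
#' ph <- generateSpinePhantom(PhantomSpec(seed = 7))
#' phiTrue(ph$truth)  # straight default centerline: 0 degrees
#' @export
generateSpinePhantom <- function(spec) {
  validObject(spec)
  shape <- spec@imageShape
  centers <- phantomCenters(spec)
  boxes <- t(apply(centers, 1, blobBox, size = spec@vertebraSize))
  if (any(boxes[, 1] < 1) || any(boxes[, 2] < 1) ||
      any(boxes[, 1] + boxes[, 3] - 1 > shape[1]) ||
      any(boxes[, 2] + boxes[, 4] - 1 > shape[2]))
    stop("invalid phantom spec: blobs would exit the image bounds")

  img <- matrix(spec@bgIntensity, shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    b <- boxes[i, ]
    rows <- b[1]:(b[1] + b[3] - 1); cols <- b[2]:(b[2] + b[4] - 1)
    inside <- blobIndicator(centers[i, ], spec@vertebraSize, rows, cols)
    img[rows, cols][inside] <- spec@fgIntensity
  }
  img <- gaussSmooth(img, 0.8)  # soften rasterized edges
  img <- withSeed(spec@seed, {
    clamp01(img + matrix(rnorm(length(img), sd = spec@noiseSd),
                         nrow(img), ncol(img)))
  })

  dcoef <- polyDeriv(spec@centerlineCoeffs)
  phi <- as.numeric(abs(atan(polyval(dcoef, centers[nrow(centers), 1])) -
                        atan(polyval(dcoef, centers[1, 1]))) * 180 / pi)
  list(image = SpineImage(img, view = "coronal"),
       truth = new("PhantomTruth", centroids = centers,
                   boxes = boxes, phiTrue = phi))
}

#' Ground-truth vertebra masks of a phantom
#'
#' Re-rasterizes each vertebra blob of the spec as a [VertebraMask-class] on
#' its ground-truth box, bypassing detection and segmentation. Useful for
#' isolating the curvature stage from segmentation error.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list of [VertebraMask-class], numbered superior to inferior.
#' @export
phantomTruthMasks <- function(spec) {
  centers <- phantomCenters(spec)
  lapply(seq_len(nrow(centers)), function(i) {
    b <- blobBox(centers[i, ], spec@vertebraSize)
    rows <- b[1]:(b[1] + b[3] - 1); cols <- b[2]:(b[2] + b[4] - 1)
    m <- blobIndicator(centers[i, ], spec@vertebraSize, rows, cols) + 0
    VertebraMask(m, offset = b[1:2], number = i)
  })
}

#' Phantom spec with a prescribed tangent angle
#'
#' Builds a quadratic centerline `col = col0 + c2 (row - r1)^2` whose tangent
#' angle between the first and last vertebra centroid equals `phiDeg`
#' (the slope at the first centroid is zero by construction). The quadratic
#' coefficient is solved by fixed-point iteration against the arc-length
#' placement of the centers.
#'
#' @param phiDeg target tangent angle, degrees (>= 0).
#' @param col0 lateral position (col) of the first centroid.
#' @param ... further arguments passed to [PhantomSpec()].
#' @return A [PhantomSpec-class] whose `phiTrue` equals `phiDeg` (to 1e-6).
#' @export
phantomSpecForAngle <- function(phiDeg, col0 = 55, ...) {
  stopifnot(phiDeg >= 0, phiDeg < 80)
  base <- PhantomSpec(centerlineCoeffs = c(col0, 0, 0), ...)
  r1 <- phantomCenters(base)[1, 1]
  if (phiDeg == 0) return(base)
  c2 <- tan(phiDeg * pi / 180) / (2 * (base@nVertebrae - 1) * base@spacingPx)
  for (iter in 1:50) {
    # expand col0 + c2 (row - r1)^2 in powers of row
    coeffs <- c(col0 + c2 * r1^2, -2 * c2 * r1, c2)
    spec <- PhantomSpec(centerlineCoeffs = coeffs, ...)
    centers <- phantomCenters(spec)
    rEnd <- centers[nrow(centers), 1]
    phiCur <- atan(2 * c2 * (rEnd - r1)) * 180 / pi
    if (abs(phiCur - phiDeg) < 1e-9) break
    c2 <- tan(phiDeg * pi / 180) / (2 * (rEnd - r1))
  }
  spec
}

#' Sample labelled training patches from a phantom
#'
#' Positive patches crop the ground-truth vertebra boxes with a small random
#' jitter (sampled with replacement when `nPos` exceeds the number of
#' vertebrae); negative patches are background crops with IoU < 0.2 against
#' every truth box -- half drawn uniformly over the image and half placed
#' near vertebrae (displaced truth boxes), so the negative class includes the
#' hard off-center windows a sliding-window scan produces. All patches are
#' bilinearly resized to the canonical window. Deterministic for a fixed
#' spec.
#'
#' @param spec a [PhantomSpec-class].
#' @param nPos,nNeg patch counts (each >= 1).
#' @param window canonical window `c(rows, cols)`.
#' @param jitterPx maximum positive-crop jitter, px.
#' @return A list: `patches` (array `window[1] x window[2] x (nPos+nNeg)`),
#'   `labels` (integer 0/1 vector, 1 = vertebra).
#' @export
generateTrainingPatches <- function(spec, nPos, nNeg, window = c(24L, 30L),
                                    jitterPx = 2L) {
  stopifnot(nPos >= 1, nNeg >= 1)
  ph <- generateSpinePhantom(spec)
  img <- pixels(ph$image)
  boxes <- truthBoxes(ph$truth)
  nr <- nrow(img); nc <- ncol(img)
  window <- as.integer(window)

  withSeed(spec@seed + 1L, {
    patches <- array(0, dim = c(window[1], window[2], nPos + nNeg))
    for (k in seq_len(nPos)) {
      b <- boxes[sample.int(nrow(boxes), 1L), ]
      top <- b[1] + sample(seq(-jitterPx, jitterPx), 1L)
      left <- b[2] + sample(seq(-jitterPx, jitterPx), 1L)
      top <- min(max(1L, top), nr - b[3] + 1L)
      left <- min(max(1L, left), nc - b[4] + 1L)
      crop <- img[top:(top + b[3] - 1L), left:(left + b[4] - 1L)]
      patches[, , k] <- resizeMatrix(crop, window[1], window[2])
    }
    for (k in seq_len(nNeg)) {
      hard <- k %% 2L == 0L
      for (try in 1:1000) {
        if (hard) {
          b <- boxes[sample.int(nrow(boxes), 1L), ]
          top <- b[1] + sample(c(-1L, 1L), 1L) *
            sample(seq(window[1] %/% 2L, window[1]), 1L)
          left <- b[2] + sample(c(-1L, 1L), 1L) *
            sample(seq(window[2] %/% 2L, window[2]), 1L)
          top <- min(max(1L, top), nr - window[1] + 1L)
          left <- min(max(1L, left), nc - window[2] + 1L)
        } else {
          top <- sample.int(nr - window[1] + 1L, 1L)
          left <- sample.int(nc - window[2] + 1L, 1L)
        }
        cand <- c(top, left, window)
        ious <- apply(boxes, 1, boxIoU, b = cand)
        if (max(ious) < 0.2) break
      }
      patches[, , nPos + k] <-
        img[top:(top + window[1] - 1L), left:(left + window[2] - 1L)]
    }
    list(patches = patches,
         labels = c(rep(1L, nPos), rep(0L, nNeg)))
  })
}

#' Detection recall against ground-truth boxes
#'
#' Greedy one-to-one matching by descending detection score: each detection
#' claims the unmatched truth box of highest IoU, provided IoU >= `iouMin`.
#'
#' @param detections a data.frame with columns `top`, `left`, `height`,
#'   `width`, `score` (as returned by [detectVertebrae()]); may have 0 rows.
#' @param truth a [PhantomTruth-class] (or a box matrix).
#' @param iouMin minimum IoU for a match, in (0, 1).
#' @return Fraction of truth boxes matched, in `[0, 1]`.
#' @export
detectionRecall <- function(detections, truth, iouMin = 0.5) {
  stopifnot(iouMin > 0, iouMin < 1)
  boxes <- if (is(truth, "PhantomTruth")) truthBoxes(truth) else truth
  if (is.null(dim(boxes)) || nrow(boxes) == 0)
    stop("ground truth contains no boxes")
  if (nrow(detections) == 0) return(0)
  det <- detections[order(-detections$score), , drop = FALSE]
  taken <- rep(FALSE, nrow(boxes))
  matched <- 0L
  for (i in seq_len(nrow(det))) {
    d <- as.numeric(det[i, c("top", "left", "height", "width")])
    ious <- apply(boxes, 1, boxIoU, b = d)
    ious[taken] <- -1
    j <- which.max(ious)
    if (ious[j] >= iouMin) {
      taken[j] <- TRUE
      matched <- matched + 1L
    }
  }
  matched / nrow(boxes)
}

#' Mean Euclidean centroid localisation error
#'
#' Mean over ordered pairs of `spacingMm * sqrt(drow^2 + dcol^2)`.
#'
#' @param extracted,truth numeric matrices (`row`, `col`), equal row counts,
#'   ordered correspondence.
#' @param spacingMm pixel spacing in mm/px (1 reports the error in px).
#' @return Mean error (mm, or px when `spacingMm = 1`).
#' @export
centroidError <- function(extracted, truth, spacingMm = 1) {
  extracted <- rbind(extracted); truth <- rbind(truth)
  if (nrow(extracted) != nrow(truth))
    stop("extracted and truth centroid lists differ in length")
  d <- sqrt(rowSums((extracted[, 1:2, drop = FALSE] -
                     truth[, 1:2, drop = FALSE])^2))
  mean(spacingMm * d)
}

#' ROC curve points over all score thresholds
#'
#' @param scoresPos,scoresNeg non-empty numeric score vectors of positive and
#'   negative samples (higher = more positive).
#' @return A data.frame (`fpr`, `tpr`) forming a monotone non-decreasing
#'   curve from (0, 0) to (1, 1).
#' @export
rocPoints <- function(scoresPos, scoresNeg) {
  if (length(scoresPos) == 0 || length(scoresNeg) == 0)
    stop("both score lists must be non-empty")
  thr <- sort(unique(c(scoresPos, scoresNeg)), decreasing = TRUE)
  pts <- data.frame(
    fpr = c(0, vapply(thr, function(t) mean(scoresNeg >= t), 0), 1),
    tpr = c(0, vapply(thr, function(t) mean(scoresPos >= t), 0), 1))
  pts <- unique(pts[order(pts$fpr, pts$tpr), ])
  rownames(pts) <- NULL
  pts
}
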