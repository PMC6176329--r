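#' @include AllClasses.R
NULL

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise clipped-histogram equalization with bilinear interpolation
#' between tile mappings, used to enhance low-contrast vertebral regions
#' before edge-based segmentation. The image is reflect-padded to a multiple
#' of the tile grid and cropped back. The clip limit is a fraction of the
#' tile pixel count (0.01 by default).
#'
#' @param image a [SpineImage-class] or intensity matrix in `[0, 1]`.
#' @param clip clip limit as a fraction of tile pixels.
#' @param tiles tile grid `c(rows, cols)`.
#' @param bins histogram bins.
#' @return Same type as the input, intensities in `[0, 1]`.
#' @export
claheEnhance <- function(image, clip = 0.01, tiles = c(8L, 8L), bins = 256L) {
  isImg <- is(image, "SpineImage")
  m <- if (isImg) pixels(image) else image
  if (min(m) < 0 || max(m) > 1) stop("intensities must lie in [0, 1]")
  if (any(floor(dim(m) / tiles) < 2))
    stop("degenerate tile size: image too small for the tile grid")
  nr <- nrow(m); nc <- ncol(m)
  padr <- (tiles[1] - nr %% tiles[1]) %% tiles[1]
  padc <- (tiles[2] - nc %% tiles[2]) %% tiles[2]
  mp <- m
  if (padr > 0) mp <- rbind(mp, mp[nr:(nr - padr + 1), , drop = FALSE])
  if (padc > 0) mp <- cbind(mp, mp[, ncol(mp):(ncol(mp) - padc + 1),
                                   drop = FALSE])
  # EBImage's limit is in multiples of the average bin height
  out <- fromEB(EBImage::clahe(asEB(mp), nx = tiles[2], ny = tiles[1],
                               bins = bins, limit = max(clip * bins, 1)))
  out <- clamp01(out[seq_len(nr), seq_len(nc), drop = FALSE])
  if (isImg) SpineImage(out, imageView(image), pixelSpacing(image)) else out
}

#' Edge indicator function
#'
#' `g = 1 / (1 + |grad(G_sigma * I)|^2)`: close to 1 in flat regions, small
#' on strong (Gaussian-smoothed) edges. Steers the level-set contour onto
#' object boundaries. Intensities are evaluated on the 8-bit (0-255) gray
#' scale -- the scale on which the default evolution weights (`lambda`,
#' `alpha`) are calibrated in the level-set literature -- so `[0, 1]` images
#' are multiplied by 255 before the gradient.
#'
#' @param image a [SpineImage-class] or intensity matrix.
#' @param sigma Gaussian smoothing scale, px (default 1.5).
#' @return A matrix of `g` values in `(0, 1]`, with attribute `"sigma"`.
#' @export
edgeIndicator <- function(image, sigma = 1.5) {
  stopifnot(sigma > 0)
  m <- if (is(image, "SpineImage")) pixels(image) else image
  gr <- gradientRC(gaussSmooth(m * 255, sigma))
  structure(1 / (1 + gr$dr^2 + gr$dc^2), sigma = sigma)
}

#' Smoothed Dirac delta
#'
#' `(1/(2 eps)) (1 + cos(pi x / eps))` for `|x| <= eps`, 0 outside:
#' compactly supported, integrates to 1, peak `1/eps` at 0.
#'
#' @param x numeric values (typically level-set values).
#' @param eps smoothing width (> 0), default 1.5 grid units.
#' @return Values of the smoothed delta.
#' @export
smoothedDirac <- function(x, eps = 1.5) {
  stopifnot(eps > 0)
  ifelse(abs(x) <= eps, (1 + cos(pi * x / eps)) / (2 * eps), 0)
}

#' Smoothed Heaviside
#'
#' The antiderivative of [smoothedDirac()]: 0 below `-eps`, 1 above `eps`,
#' and `(1 + x/eps + sin(pi x/eps)/pi) / 2` in between, so that
#' `H' = delta_eps`.
#'
#' @inheritParams smoothedDirac
#' @return Values in `[0, 1]`.
#' @export
smoothedHeaviside <- function(x, eps = 1.5) {
  stopifnot(eps > 0)
  ifelse(x < -eps, 0,
         ifelse(x > eps, 1, (1 + x / eps + sin(pi * x / eps) / pi) / 2))
}

#' Double-well distance-regularization factor
#'
#' `d_p(s) = p'(s)/s` for the double-well potential whose minima sit at
#' `s = 0` and `s = 1`: `p'(s) = sin(2 pi s)/(2 pi)` for `s <= 1` and
#' `s - 1` for `s >= 1`. The analytic limit `d_p(0) = 1` is used at `s = 0`;
#' `d_p(1) = 0`, and `|d_p| <= 1` everywhere. This forward-and-backward
#' diffusion keeps the level-set function close to a signed distance function
#' near its zero level without reinitialization.
#'
#' @param s non-negative gradient magnitudes `|grad phi|`.
#' @return Factor values.
#' @export
dpFactor <- function(s) {
  stopifnot(all(s >= 0))
  small <- s < 1e-8
  out <- ifelse(s <= 1,
                sin(2 * pi * pmax(s, 1e-300)) / (2 * pi * pmax(s, 1e-300)),
                (s - 1) / pmax(s, 1e-300))
  out[small] <- 1
  out
}

#' Level-set parameters
#'
#' Defaults follow standard DRLSE practice for vertebra segmentation:
#' `mu = 0.04` (distance-regularization weight; the explicit scheme needs
#' `mu * dt < 1/4`), `lambda = 5` (length/edge term), `alpha = 1.5` (area
#' term; positive shrinks a contour initialized outside the object),
#' `epsilon = 1.5` (Dirac width, grid units), `sigma = 1.5` (edge-indicator
#' Gaussian scale), `c0 = 2` (binary-step initialization height). The time
#' step `dt = 3` gives `mu * dt = 0.12`, well inside the stability bound,
#' and lets a detection-box-seeded contour settle on the object boundary
#' within the default 200 iterations without the late inward creep a larger
#' step produces.
#'
#' @param mu,lambda,alpha,epsilon,sigma,dt,c0 see description.
#' @return A named list of parameters.
#' @export
drlseParams <- function(mu = 0.04, lambda = 5, alpha = 1.5, epsilon = 1.5,
                        sigma = 1.5, dt = 3, c0 = 2) {
  p <- list(mu = mu, lambda = lambda, alpha = alpha, epsilon = epsilon,
            sigma = sigma, dt = dt, c0 = c0)
  if (p$mu * p$dt >= 0.25)
    stop("stability contract violated: mu * dt must be < 1/4")
  stopifnot(p$epsilon > 0, p$sigma > 0, p$dt > 0)
  p
}

#' Initialize a level-set function from a bounding box
#'
#' Binary step initialization: `phi = -c0` inside the box, `+c0` outside,
#' so the zero level set is the box boundary and the region `phi < 0` is the
#' box interior (the inside-negative sign convention).
#'
#' @param box `c(top, left, height, width)`, 1-based closed, inside the grid.
#' @param gridShape `c(rows, cols)` of the level-set grid.
#' @param c0 initialization height (> 0).
#' @return A numeric matrix `phi`.
#' @export
initLevelSet <- function(box, gridShape, c0 = 2) {
  box <- as.integer(box)
  if (box[3] < 2 || box[4] < 2) stop("degenerate box")
  if (box[1] < 1 || box[2] < 1 || box[1] + box[3] - 1 > gridShape[1] ||
      box[2] + box[4] - 1 > gridShape[2])
    stop("box outside the level-set grid")
  phi <- matrix(c0, gridShape[1], gridShape[2])
  phi[box[1]:(box[1] + box[3] - 1), box[2]:(box[2] + box[4] - 1)] <- -c0
  phi
}

# Mirror the outermost rows/cols onto the third-from-edge values (Neumann
# boundary condition for the explicit scheme).
neumannBC <- function(phi) {
  nr <- nrow(phi); nc <- ncol(phi)
  phi[c(1, nr), ] <- phi[c(3, nr - 2), ]
  phi[, c(1, nc)] <- phi[, c(3, nc - 2)]
  phi
}

divergence <- function(fr, fc) {
  gradientRC(fr)$dr + gradientRC(fc)$dc
}

laplacian5 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1, seq_len(nr - 1)), ]
  dn <- m[c(seq_len(nr)[-1], nr), ]
  lf <- m[, c(1, seq_len(nc - 1))]
  rt <- m[, c(seq_len(nc)[-1], nc)]
  up + dn + lf + rt - 4 * m
}

#' One explicit-Euler DRLSE step
#'
#' Updates `phi` by `dt` times the gradient flow
#' `mu div(d_p(|grad phi|) grad phi) + lambda delta_eps(phi)
#' div(g grad phi / |grad phi|) + alpha g delta_eps(phi)`,
#' with central differences, Neumann boundaries and a small-constant guard on
#' `|grad phi|`. The distance-regularization term is evaluated as
#' `div((d_p - 1) grad phi) + laplacian(phi)`.
#'
#' @param phi level-set matrix (inside negative).
#' @param g edge-indicator matrix from [edgeIndicator()] (same shape).
#' @param params a [drlseParams()].
#' @return The updated `phi`.
#' @export
evolveStep <- function(phi, g, params = drlseParams()) {
  phi <- neumannBC(phi)
  gp <- gradientRC(phi)
  s <- sqrt(gp$dr^2 + gp$dc^2)
  guard <- 1e-10
  Nr <- gp$dr / (s + guard); Nc <- gp$dc / (s + guard)
  dp <- dpFactor(s)
  distReg <- divergence((dp - 1) * gp$dr, (dp - 1) * gp$dc) + laplacian5(phi)
  gg <- gradientRC(g)
  dirac <- smoothedDirac(phi, params$epsilon)
  curv <- divergence(Nr, Nc)
  edgeTerm <- dirac * (gg$dr * Nr + gg$dc * Nc) + dirac * g * curv
  areaTerm <- params$alpha * g * dirac
  out <- phi + params$dt * (params$mu * distReg +
                            params$lambda * edgeTerm + areaTerm)
  if (any(!is.finite(out)))
    stop(sprintf(paste0("level-set evolution diverged (non-finite phi) with ",
                        "mu=%g, lambda=%g, alpha=%g, epsilon=%g, dt=%g"),
                 params$mu, params$lambda, params$alpha, params$epsilon,
                 params$dt))
  out
}

#' Run DRLSE for a number of iterations
#'
#' @inheritParams evolveStep
#' @param nIter number of explicit steps (default 200).
#' @return The evolved `phi`.
#' @export
evolveLevelSet <- function(phi, g, params = drlseParams(), nIter = 200L) {
  for (i in seq_len(nIter)) phi <- evolveStep(phi, g, params)
  phi
}

largestComponent <- function(mask) {
  if (sum(mask) == 0) return(mask)
  lab <- fromEB(EBImage::bwlabel(asEB(mask)))
  sizes <- tabulate(lab[lab > 0])
  (lab == which.max(sizes)) + 0
}

#' Segment detected vertebrae by level-set evolution
#'
#' Per detection: the image is contrast-enhanced (CLAHE, once for the whole
#' image), a region of interest is cut around the detection box (padded by
#' `2 * pad` of the box size on each side), the edge indicator is computed,
#' the level set is initialized on the detection box dilated by `pad` -- so
#' a vertebra that sticks slightly out of an imperfectly localized box still
#' starts inside the contour, which the positive area term then contracts
#' onto the boundary -- and evolved for `nIter` steps; the final mask is the
#' largest connected component of `phi < 0`. Masks carry the source
#' detection number. An empty mask raises a warning for that detection, not
#' a failure.
#'
#' @param image a [SpineImage-class] or intensity matrix.
#' @param detections detection data.frame from [detectVertebrae()] (columns
#'   `number`, `top`, `left`, `height`, `width`); at least one row.
#' @param params a [drlseParams()].
#' @param nIter evolution steps per vertebra (default 200).
#' @param pad ROI padding as a fraction of the box size.
#' @param clahe apply CLAHE enhancement first (default TRUE).
#' @return A list of [VertebraMask-class].
#' @export
segmentVertebrae <- function(image, detections, params = drlseParams(),
                             nIter = 200L, pad = 0.2, clahe = TRUE) {
  m <- if (is(image, "SpineImage")) pixels(image) else image
  if (nrow(detections) < 1) stop("at least one detection is required")
  if (clahe) m <- claheEnhance(m)
  out <- vector("list", nrow(detections))
  for (i in seq_len(nrow(detections))) {
    d <- detections[i, ]
    pr <- pmax(2L, round(c(d$height, d$width) * pad))
    top <- max(1L, d$top - 2L * pr[1]); left <- max(1L, d$left - 2L * pr[2])
    bot <- min(nrow(m), d$top + d$height - 1L + 2L * pr[1])
    rgt <- min(ncol(m), d$left + d$width - 1L + 2L * pr[2])
    roi <- m[top:bot, left:rgt, drop = FALSE]
    g <- edgeIndicator(roi, params$sigma)
    # initial contour: the detection box dilated by the padding, clipped to
    # leave a one-pixel rim inside the ROI
    box <- c(max(2L, d$top - pr[1] - top + 1L),
             max(2L, d$left - pr[2] - left + 1L),
             d$height + 2L * pr[1], d$width + 2L * pr[2])
    box[3] <- min(box[3], nrow(roi) - box[1])
    box[4] <- min(box[4], ncol(roi) - box[2])
    phi <- initLevelSet(box, dim(roi), params$c0)
    phi <- evolveLevelSet(phi, g, params, nIter)
    mask <- largestComponent((phi < 0) + 0)
    if (sum(mask) == 0)
      warning("empty mask after evolution for detection ", d$number)
    out[[i]] <- VertebraMask(mask, offset = c(top, left),
                             number = as.integer(d$number))
  }
  out
}
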