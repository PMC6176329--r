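#' @include AllClasses.R
NULL

# Haar template kinds as sign grids: each template divides its placement box
# into a gr x gc cell grid; +1 cells are white, -1 black. The feature value
# is sum(white) - sum(black).
.HAAR_KINDS <- list(
  "edge-horizontal"   = matrix(c(1, -1), 2, 1),
  "edge-vertical"     = matrix(c(1, -1), 1, 2),
  "line-horizontal"   = matrix(c(1, -1, 1), 3, 1),
  "line-vertical"     = matrix(c(1, -1, 1), 1, 3),
  "line-diag1"        = matrix(c(1, -1, -1, 1), 2, 2),
  "line-diag2"        = matrix(c(-1, 1, 1, -1), 2, 2),
  "center-surround-1" = matrix(c(1, 1, 1, 1, -1, 1, 1, 1, 1), 3, 3),
  "center-surround-2" = matrix(c(-1, -1, -1, -1, 1, -1, -1, -1, -1), 3, 3))

#' Descriptor configuration for the canonical window
#'
#' Fixes the geometry of the fused Haar-like / LBP / HOG descriptor: the Haar
#' placement pool (the 8 template kinds at a few scales on a coarse position
#' grid), the LBP subregion grid, and the HOG cell/bin layout. A fixed config
#' implies a fixed feature-vector length.
#'
#' @param window canonical window `c(rows, cols)`; default 90 x 80.
#' @param haarScales placement-box sizes as fractions of the window.
#' @param haarStrideFrac placement stride as a fraction of the window.
#' @param lbpGrid LBP subregion grid `c(gr, gc)`.
#' @param hogCell HOG cell size, px (square).
#' @param hogBins number of unsigned orientation bins.
#' @return A named list (class `"featureConfig"`).
#' @export
featureConfig <- function(window = c(90L, 80L),
                          haarScales = c(1 / 2, 1 / 3, 1 / 4),
                          haarStrideFrac = 1 / 4,
                          lbpGrid = c(4L, 4L), hogCell = 8L, hogBins = 9L) {
  window <- as.integer(window)
  stopifnot(length(window) == 2, all(window >= 8),
            all(haarScales > 0), all(haarScales <= 1),
            haarStrideFrac > 0, length(lbpGrid) == 2,
            hogCell >= 2, hogBins >= 2)
  if (any(window %/% as.integer(lbpGrid) < 3))
    stop("LBP subregions would be smaller than 3x3 for this window")
  if (any(window < hogCell))
    stop("window smaller than one HOG cell")
  structure(list(window = window, haarScales = haarScales,
                 haarStrideFrac = haarStrideFrac,
                 lbpGrid = as.integer(lbpGrid),
                 hogCell = as.integer(hogCell), hogBins = as.integer(hogBins)),
            class = "featureConfig")
}

#' Integral image (summed-area table)
#'
#' Zero-padded cumulative-sum table: entry `(i+1, j+1)` is the sum of
#' `patch[1:i, 1:j]`, so any rectangle sum costs four lookups
#' (see [rectSum()]).
#'
#' @param patch a numeric matrix.
#' @return A `(rows+1) x (cols+1)` numeric matrix.
#' @examples
#' ii <- integralImage(matrix(1, 4, 4))
#' rectSum(ii, 1, 1, 4, 4)  # 16
#' @export
integralImage <- function(patch) {
  stopifnot(is.matrix(patch), length(patch) > 0)
  .cpp_integral_image(patch)
}

#' Rectangle sum from an integral image
#'
#' @param ii an [integralImage()] table.
#' @param top,left 1-based corner of the rectangle.
#' @param height,width rectangle extent; the rectangle covers rows
#'   `top..top+height-1`.
#' @return The sum of the patch over the rectangle.
#' @export
rectSum <- function(ii, top, left, height, width) {
  # cbind indexing keeps this vectorized over multiple rectangles
  ii[cbind(top + height, left + width)] - ii[cbind(top, left + width)] -
    ii[cbind(top + height, left)] + ii[cbind(top, left)]
}

# Signed sub-rectangles of one Haar template placed at `box` =
# c(top, left, height, width); box dims must be divisible by the sign grid.
haarRects <- function(kind, box) {
  signs <- .HAAR_KINDS[[kind]]
  if (is.null(signs)) stop("unknown Haar template kind: ", kind)
  gr <- nrow(signs); gc <- ncol(signs)
  if (box[3] %% gr != 0 || box[4] %% gc != 0)
    stop("placement box dims must be multiples of the template grid")
  ch <- box[3] %/% gr; cw <- box[4] %/% gc
  out <- matrix(0L, gr * gc, 5)
  k <- 0L
  for (i in seq_len(gr)) for (j in seq_len(gc)) {
    k <- k + 1L
    out[k, ] <- c(box[1] + (i - 1L) * ch, box[2] + (j - 1L) * cw,
                  ch, cw, signs[i, j])
  }
  out
}

#' A single Haar-like feature value
#'
#' White-minus-black rectangle intensity difference, evaluated from an
#' integral image.
#'
#' @param ii an [integralImage()] of the patch.
#' @param kind template kind: `"edge-horizontal"`, `"edge-vertical"`,
#'   `"line-horizontal"`, `"line-vertical"`, `"line-diag1"`, `"line-diag2"`,
#'   `"center-surround-1"` or `"center-surround-2"`.
#' @param box placement `c(top, left, height, width)` within the patch; its
#'   dims must be multiples of the template's cell grid.
#' @return sum(white region) - sum(black region).
#' @export
haarFeature <- function(ii, kind, box) {
  if (box[1] < 1 || box[2] < 1 ||
      box[1] + box[3] > nrow(ii) || box[2] + box[4] > ncol(ii))
    stop("Haar placement box out of patch bounds")
  rects <- haarRects(kind, as.integer(box))
  sum(rects[, 5] * rectSum(ii, rects[, 1], rects[, 2], rects[, 3], rects[, 4]))
}

# Build the Haar placement pool for a config: every kind at every scale,
# placed on a grid with stride `haarStrideFrac * window`, box dims rounded
# down to multiples of the template grid. Returns list(nFeatures, rects,
# table) with `rects` in the layout .cpp_haar_eval expects.
haarPool <- function(config) {
  win <- config$window
  stride <- pmax(1L, as.integer(floor(win * config$haarStrideFrac)))
  rows <- list(); feats <- list()
  fid <- 0L
  for (kind in names(.HAAR_KINDS)) {
    signs <- .HAAR_KINDS[[kind]]
    gr <- nrow(signs); gc <- ncol(signs)
    for (s in config$haarScales) {
      h <- (as.integer(floor(win[1] * s)) %/% gr) * gr
      w <- (as.integer(floor(win[2] * s)) %/% gc) * gc
      if (h < gr || w < gc) next
      for (top in seq(1L, win[1] - h + 1L, by = stride[1])) {
        for (left in seq(1L, win[2] - w + 1L, by = stride[2])) {
          fid <- fid + 1L
          r <- haarRects(kind, c(top, left, h, w))
          rows[[fid]] <- cbind(fid, r)
          feats[[fid]] <- data.frame(kind = kind, top = top, left = left,
                                     height = h, width = w)
        }
      }
    }
  }
  list(nFeatures = fid,
       rects = do.call(rbind, rows),
       table = do.call(rbind, feats))
}

#' LBP code of one 3x3 neighbourhood
#'
#' `code = sum_p 2^p [f_p >= f_c]` over the 8 neighbours of the centre pixel,
#' with neighbour order p = 0..7 clockwise from the top-left corner:
#' (-1,-1), (-1,0), (-1,1), (0,1), (1,1), (1,0), (1,-1), (0,-1).
#' Ties count as 1.
#'
#' @param neighborhood a 3x3 numeric matrix; the centre is `[2, 2]`.
#' @return Integer code in 0..255.
#' @export
lbpCode <- function(neighborhood) {
  stopifnot(identical(dim(neighborhood), c(3L, 3L)))
  .cpp_lbp_codes(neighborhood)[1, 1]
}

#' LBP texture descriptor of a patch
#'
#' Codes every interior pixel (full 3x3 neighbourhood within the patch),
#' partitions the patch into a `grid` of subregions, and concatenates the
#' 256-bin code histograms subregion by subregion (row-major). Each
#' subregion histogram sums to the number of patch-interior pixels it holds.
#'
#' @param patch numeric matrix, at least 3x3.
#' @param grid subregion grid `c(gr, gc)`; every subregion must be >= 3x3.
#' @return Numeric vector of length `gr * gc * 256`.
#' @export
lbpDescriptor <- function(patch, grid = c(4L, 4L)) {
  nr <- nrow(patch); nc <- ncol(patch)
  gr <- grid[1]; gc <- grid[2]
  if (nr %/% gr < 3 || nc %/% gc < 3)
    stop("subregion smaller than 3x3; reduce the LBP grid")
  codes <- .cpp_lbp_codes(patch)  # (nr-2) x (nc-2), for pixels 2..nr-1
  rowEdges <- round(seq(0, nr, length.out = gr + 1))
  colEdges <- round(seq(0, nc, length.out = gc + 1))
  # subregion of interior pixel (i, j): i in 2..nr-1 maps to codes[i-1, ]
  out <- numeric(gr * gc * 256)
  block <- 0L
  for (bi in seq_len(gr)) {
    ri <- intersect(seq(rowEdges[bi] + 1, rowEdges[bi + 1]), 2:(nr - 1))
    for (bj in seq_len(gc)) {
      ci <- intersect(seq(colEdges[bj] + 1, colEdges[bj + 1]), 2:(nc - 1))
      h <- tabulate(codes[ri - 1, ci - 1, drop = FALSE] + 1L, nbins = 256)
      out[block * 256 + seq_len(256)] <- h
      block <- block + 1L
    }
  }
  out
}

#' HOG descriptor of a patch
#'
#' Central-difference gradients (replicated borders), unsigned orientation in
#' `[0, pi)` hard-binned into `bins` bins with magnitude votes, accumulated
#' per `cell x cell` cell; 2x2-cell blocks (stride one cell) are L2-normalized
#' with a small-constant guard and concatenated. A constant patch yields an
#' all-zero descriptor.
#'
#' @param patch numeric matrix, at least one cell in each dimension.
#' @param cell cell size in px (default 8).
#' @param bins orientation bins (default 9).
#' @return Numeric vector of block-normalized cell histograms.
#' @export
hogDescriptor <- function(patch, cell = 8L, bins = 9L) {
  if (nrow(patch) < cell || ncol(patch) < cell)
    stop("patch smaller than one HOG cell")
  cells <- .cpp_hog_cells(patch, as.integer(cell), as.integer(bins))
  d <- dim(cells)
  cr <- d[1]; cc <- d[2]
  br <- max(1L, cr - 1L); bc <- max(1L, cc - 1L)
  out <- numeric(0)
  for (i in seq_len(br)) {
    for (j in seq_len(bc)) {
      ri <- i:min(i + 1L, cr); ci <- j:min(j + 1L, cc)
      v <- as.numeric(cells[ri, ci, ])
      out <- c(out, v / sqrt(sum(v^2) + 1e-10))
    }
  }
  out
}

# Raw (unnormalized) fused feature vector of a window-sized patch.
# The Haar pool is cached per config within the calling context by passing
# `pool` explicitly where throughput matters.
rawFeatureVector <- function(patch, config, pool = haarPool(config)) {
  if (!identical(dim(patch), as.integer(config$window)))
    stop("patch shape ", paste(dim(patch), collapse = "x"),
         " does not match the configured window ",
         paste(config$window, collapse = "x"))
  ii <- .cpp_integral_image(patch)
  fHaar <- .cpp_haar_eval(ii, pool$rects, pool$nFeatures)
  fLbp <- lbpDescriptor(patch, config$lbpGrid)
  fHog <- hogDescriptor(patch, config$hogCell, config$hogBins)
  structure(c(fHaar, fLbp, fHog),
            blockOffsets = c(haar = 1L,
                             lbp = length(fHaar) + 1L,
                             hog = length(fHaar) + length(fLbp) + 1L))
}

#' Fused feature vector of a patch
#'
#' Concatenates the Haar-like, LBP and HOG descriptor blocks (in that order)
#' and, when normalization statistics are supplied, standardizes each feature
#' with the training-set mean and standard deviation stored in the model.
#' A pure function: identical patches give identical vectors.
#'
#' @param patch numeric matrix at the canonical window size.
#' @param config a [featureConfig()].
#' @param center,scale optional per-feature standardization statistics (from
#'   [fitFeatureNormalization()]); both or neither.
#' @return Numeric feature vector with a `blockOffsets` attribute giving the
#'   start index of each descriptor block.
#' @export
extractFeatures <- function(patch, config, center = NULL, scale = NULL) {
  v <- rawFeatureVector(patch, config)
  if (!is.null(center)) {
    off <- attr(v, "blockOffsets")
    v <- structure((v - center) / scale, blockOffsets = off)
  }
  v
}

# Raw feature matrix (n x F) of a patch array (h x w x n).
featureMatrix <- function(patches, config, pool = haarPool(config)) {
  n <- dim(patches)[3]
  first <- rawFeatureVector(patches[, , 1], config, pool)
  X <- matrix(0, n, length(first))
  X[1, ] <- first
  if (n > 1) for (k in 2:n)
    X[k, ] <- rawFeatureVector(patches[, , k], config, pool)
  attr(X, "blockOffsets") <- attr(first, "blockOffsets")
  X
}

#' Fit per-feature z-score normalization statistics
#'
#' Means and standard deviations per feature column; (near-)constant features
#' get unit scale so they standardize to zero rather than dividing by zero.
#' Z-scoring is monotone per feature, so decision-stump training is
#' unaffected, but the fused descriptor blocks become comparable in scale.
#'
#' @param X raw feature matrix (samples x features).
#' @return A list with `center` and `scale` numeric vectors.
#' @export
fitFeatureNormalization <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

applyNormalization <- function(X, norm) {
  sweep(sweep(X, 2, norm$center), 2, norm$scale, "/")
}
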