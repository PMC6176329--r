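#' @include AllGenerics.R
NULL

# Run code under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# x first so pmin/pmax keep the dim attribute
clamp01 <- function(x) pmax(pmin(x, 1), 0)

#' Intersection-over-union of two bounding boxes
#'
#' Boxes are `(top, left, height, width)`, 1-based and closed.
#'
#' @param a,b numeric vectors of length 4.
#' @return IoU in `[0, 1]`.
#' @export
boxIoU <- function(a, b) {
  ri <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  ci <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ri * ci
  uni <- a[3] * a[4] + b[3] * b[4] - inter
  if (uni <= 0) return(0)
  inter / uni
}

# --- EBImage bridge -------------------------------------------------------
# Our matrices are (row, col); EBImage images are (x = col, y = row), so
# every crossing transposes.
asEB <- function(m) EBImage::Image(t(m))
fromEB <- function(img) t(EBImage::imageData(img))

# Bilinear resize of a (row, col) matrix to `rows` x `cols`.
resizeMatrix <- function(m, rows, cols) {
  if (nrow(m) == rows && ncol(m) == cols) return(m)
  fromEB(EBImage::resize(asEB(m), w = cols, h = rows))
}

# Separable Gaussian smoothing with reflected boundaries, implemented as a
# pair of dense banded operators; exact and dependency-light for the modest
# image sizes this package works at.
gaussOperator <- function(n, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  op <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - half):(i + half)
    # reflect indices back into 1..n
    idx <- ifelse(idx < 1, 2 - idx, idx)
    idx <- ifelse(idx > n, 2 * n - idx, idx)
    for (j in seq_along(idx)) op[i, idx[j]] <- op[i, idx[j]] + k[j]
  }
  op
}

gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  gaussOperator(nrow(m), sigma) %*% m %*% t(gaussOperator(ncol(m), sigma))
}

# Central-difference gradients with replicated borders; returns list(dr, dc)
# (derivative along rows, along cols).
gradientRC <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1, seq_len(nr - 1)), , drop = FALSE]
  dn <- m[c(seq_len(nr)[-1], nr), , drop = FALSE]
  lf <- m[, c(1, seq_len(nc - 1)), drop = FALSE]
  rt <- m[, c(seq_len(nc)[-1], nc), drop = FALSE]
  list(dr = (dn - up) / 2, dc = (rt - lf) / 2)
}

# Evaluate a polynomial with coefficients in increasing order of power.
polyval <- function(coeffs, x) {
  out <- numeric(length(x))
  for (k in seq_along(coeffs)) out <- out + coeffs[k] * x^(k - 1)
  out
}

# Derivative coefficients of a polynomial (increasing-order coefficients).
polyDeriv <- function(coeffs) {
  if (length(coeffs) <= 1) return(0)
  coeffs[-1] * seq_len(length(coeffs) - 1)
}
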