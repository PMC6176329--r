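test_that("mask centroids equal the direct double-sum", {
  m <- matrix(0, 10, 12); m[2:5, 3:8] <- 1
  expect_equal(extractCentroid(m), c(row = 3.5, col = 5.5))
  single <- matrix(0, 10, 12); single[7, 9] <- 1
  expect_equal(extractCentroid(single), c(row = 7, col = 9))
  set.seed(13)
  blob <- matrix(rbinom(15 * 11, 1, 0.3), 15, 11)
  blob[4, 5] <- 1
  num <- c(0, 0); den <- 0
  for (i in 1:15) for (j in 1:11) {
    num <- num + c(i, j) * blob[i, j]; den <- den + blob[i, j]
  }
  expect_identical(unname(extractCentroid(blob)), num / den)
  expect_error(extractCentroid(matrix(0, 3, 3)), "empty")
  # ROI offset moves the centroid into image coordinates
  vm <- VertebraMask(m, offset = c(11L, 21L), number = 2L)
  expect_equal(extractCentroid(vm), c(row = 13.5, col = 25.5))
})

test_that("fit quality reproduces the R^2 / RMSE definitions", {
  q <- fitQuality(c(1, 2, 3), c(1, 2, 4))
  expect_equal(q$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(q$rSquared, 0.5, tolerance = 1e-12)
  perfect <- fitQuality(c(2, 5), c(2, 5))
  expect_equal(perfect$rSquared, 1)
  expect_equal(perfect$rmse, 0)
})

test_that("the least-squares spinal curve reproduces exact polynomials", {
  rows <- c(10, 30, 55, 80, 100)
  cols <- 3 + 0.2 * rows - 0.001 * rows^2
  curve <- fitSpineCurve(cbind(rows, cols), degree = 2)
  expect_equal(curve@rSquared, 1, tolerance = 1e-9)
  expect_equal(curve@rmse, 0, tolerance = 1e-7)
  expect_equal(curve@coefficients, c(3, 0.2, -0.001), tolerance = 1e-9)
  expect_equal(curve@domain, c(10, 100))
  # collinear centroids, degree 1: slope equals the two-point slope
  lin <- fitSpineCurve(cbind(c(5, 25, 45), c(7, 17, 27)), degree = 1)
  expect_equal(lin@coefficients[2], 0.5, tolerance = 1e-12)
  expect_error(fitSpineCurve(cbind(c(1, 2), c(0, 1)), degree = 2),
               "at least")
  expect_error(fitSpineCurve(cbind(c(1, 1, 2), c(0, 1, 2))), "duplicate")
  # degree defaults: 3 for >= 5 points, 2 for 3-4, 1 for 2
  expect_equal(fitSpineCurve(cbind(rows, cols))@degree, 3L)
  expect_equal(fitSpineCurve(cbind(rows[1:3], cols[1:3]))@degree, 2L)
  expect_equal(fitSpineCurve(cbind(rows[1:2], cols[1:2]))@degree, 1L)
})

test_that("pointwise curvature matches analytic derivatives", {
  lin <- fitSpineCurve(cbind(c(0, 10), c(0, 5)), degree = 1)
  expect_equal(curvatureAt(lin, c(1, 5, 9)), rep(0, 3))
  # y = x^2 at x = 0: k = 2
  par <- fitSpineCurve(cbind(c(-1, 0, 1), c(1, 0, 1)), degree = 2)
  expect_equal(curvatureAt(par, 0), 2, tolerance = 1e-9)
  # degree-3 fit against a symbolic-derivative oracle
  co <- c(2, -1, 0.05, 0.002)
  x <- c(1, 3, 6, 10, 15)
  cub <- fitSpineCurve(cbind(x, co[1] + co[2] * x + co[3] * x^2 +
                               co[4] * x^3), degree = 3)
  d1 <- function(t) co[2] + 2 * co[3] * t + 3 * co[4] * t^2
  d2 <- function(t) 2 * co[3] + 6 * co[4] * t
  for (t in c(2.3, 7.7, 12.1))
    expect_equal(curvatureAt(cub, t), d2(t) / (1 + d1(t)^2)^1.5,
                 tolerance = 1e-10)
})

test_that("the tangent angle's quadrature equals the arctan closed form", {
  straight <- fitSpineCurve(cbind(c(0, 50), c(10, 35)), degree = 1)
  expect_equal(curvatureAngle(straight), 0)
  # y = x^2 on [0, 1]: phi = arctan(2)
  par <- fitSpineCurve(cbind(c(0, 0.5, 1), c(0, 0.25, 1)), degree = 2)
  expect_equal(curvatureAngle(par), atan(2) * 180 / pi, tolerance = 1e-9)
  expect_equal(curvatureAngleQuadrature(par), curvatureAngle(par),
               tolerance = 1e-6)
  # 100 random cubic curves: quadrature vs closed form to 1e-6 degrees
  set.seed(17)
  for (k in 1:100) {
    co <- rnorm(4) * c(10, 0.5, 0.02, 0.001)
    x <- sort(runif(5, 0, 60))
    y <- co[1] + co[2] * x + co[3] * x^2 + co[4] * x^3
    cv <- fitSpineCurve(cbind(x, y), degree = 3)
    expect_equal(curvatureAngleQuadrature(cv), curvatureAngle(cv),
                 tolerance = 1e-6)
  }
})

test_that("the tangent angle is invariant to translation and reflection", {
  set.seed(18)
  cent <- cbind(seq(10, 200, length.out = 7),
                30 + 0.1 * seq(10, 200, length.out = 7) +
                  rnorm(7, sd = 0.5))
  phi0 <- curvatureAngle(fitSpineCurve(cent))
  shifted <- cent + matrix(rep(c(40, -12), each = 7), 7, 2)
  expect_equal(curvatureAngle(fitSpineCurve(shifted)), phi0,
               tolerance = 1e-8)
  mirrored <- cbind(cent[, 1], -cent[, 2])
  expect_equal(curvatureAngle(fitSpineCurve(mirrored)), phi0,
               tolerance = 1e-8)
})

test_that("diagnosis reproduces the published decisions and boundaries", {
  # published view/angle -> label rows
  cases <- list(
    list(40.4, "sagittal", "lumbar", "normal"),
    list(30.5, "coronal", "lumbar", "abnormal"),
    list(3.2, "coronal", "lumbar", "normal"),
    list(44.6, "sagittal", "lumbar", "normal"),
    list(55.2, "coronal", "thoracic", "abnormal"),
    list(2.6, "coronal", "cervical", "normal"))
  for (cs in cases)
    expect_equal(diagnosis(diagnoseCurvature(cs[[1]], cs[[2]], cs[[3]])),
                 cs[[4]], info = paste(cs[[2]], cs[[1]]))

  # coronal boundary is inclusive: 10 degrees is scoliosis
  expect_equal(diagnosis(diagnoseCurvature(10, "coronal")), "abnormal")
  expect_equal(diagnosis(diagnoseCurvature(9.9, "coronal")), "normal")

  # truth-table oracle around every sagittal rule boundary
  ranges <- list(cervical = c(35, 45), thoracic = c(20, 45),
                 lumbar = c(40, 60))
  for (region in names(ranges)) {
    rng <- ranges[[region]]
    for (b in rng) for (d in c(-0.1, 0, 0.1)) {
      phi <- b + d
      want <- if (phi >= rng[1] && phi <= rng[2]) "normal" else "abnormal"
      expect_equal(diagnosis(diagnoseCurvature(phi, "sagittal", region)),
                   want, info = sprintf("%s %.1f", region, phi))
    }
  }
  expect_error(diagnoseCurvature(20, "sagittal"), "region")
})

test_that("analyzeSpine wires centroids, fit, angle and rules together", {
  mkMask <- function(r, c, number) {
    m <- matrix(0, 9, 9); m[4:6, 4:6] <- 1
    VertebraMask(m, offset = c(r - 4L, c - 4L), number = number)
  }
  # collinear centroids: angle 0, coronal normal
  masks <- lapply(1:5, function(k) mkMask(10L + 30L * k, 20L + 3L * k, k))
  rep0 <- analyzeSpine(masks, view = "coronal")
  expect_equal(curvatureAngle(rep0), 0, tolerance = 1e-8)
  expect_equal(diagnosis(rep0), "normal")
  expect_gte(rep0@rSquared, 0)
  expect_gte(rep0@rmse, 0)
  # mask numbering, not list order, fixes the superior-inferior ordering
  repShuffled <- analyzeSpine(masks[c(3, 1, 5, 2, 4)], view = "coronal")
  expect_equal(curvatureAngle(repShuffled), curvatureAngle(rep0),
               tolerance = 1e-10)

  # a phantom with a built-in 30-degree angle, analyzed from its own
  # ground-truth masks, recovers the angle and the scoliosis label
  sp <- phantomSpecForAngle(30, seed = 23)
  rep30 <- analyzeSpine(phantomTruthMasks(sp), view = "coronal")
  expect_lt(abs(curvatureAngle(rep30) - 30), 2)
  expect_equal(diagnosis(rep30), "abnormal")
  expect_equal(rep30@nCentroids, 8L)
})
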