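test_that("phantom generation is deterministic and respects its spec", {
  sp <- PhantomSpec(seed = 11)
  a <- generateSpinePhantom(sp)
  b <- generateSpinePhantom(sp)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(centroids(a$truth), centroids(b$truth))
  expect_equal(nrow(centroids(a$truth)), 8)
  expect_true(all(pixels(a$image) >= 0 & pixels(a$image) <= 1))
  # blob centers lie on the centerline
  cent <- centroids(a$truth)
  expect_equal(unname(cent[, 2]), rep(60, nrow(cent)), tolerance = 1e-12)
})

test_that("an overflowing centerline is rejected", {
  sp <- PhantomSpec(centerlineCoeffs = c(250, 0, 0), seed = 1)
  expect_error(generateSpinePhantom(sp), "bounds")
  sp2 <- PhantomSpec(nVertebrae = 12, imageShape = c(300, 260), seed = 1)
  expect_error(generateSpinePhantom(sp2), "bounds")
})

test_that("phiTrue matches the closed-form tangent angle of the centerline", {
  # straight spine and constant-slope spine both have zero tangent angle
  expect_equal(phiTrue(generateSpinePhantom(PhantomSpec(seed = 2))$truth), 0)
  sloped <- PhantomSpec(centerlineCoeffs = c(40, 0.3, 0),
                        imageShape = c(420, 260), seed = 2)
  expect_equal(phiTrue(generateSpinePhantom(sloped)$truth), 0)

  # quadratic centerline: independent symbolic-derivative oracle
  co <- c(50, -0.05, 4e-4)
  sp <- PhantomSpec(centerlineCoeffs = co, seed = 3)
  tr <- generateSpinePhantom(sp)$truth
  rFirst <- unname(centroids(tr)[1, 1])
  rLast <- unname(centroids(tr)[nrow(centroids(tr)), 1])
  slope <- function(r) co[2] + 2 * co[3] * r  # d/dr by hand
  oracle <- abs(atan(slope(rLast)) - atan(slope(rFirst))) * 180 / pi
  expect_equal(phiTrue(tr), oracle, tolerance = 1e-10)

  # and agrees with numeric quadrature of the tangent-angle integral
  quad <- integrate(function(r) 2 * co[3] / (1 + slope(r)^2),
                    rFirst, rLast, rel.tol = 1e-12)$value * 180 / pi
  expect_equal(phiTrue(tr), abs(quad), tolerance = 1e-6)
})

test_that("phantomSpecForAngle hits the requested tangent angle", {
  for (ang in c(0, 5, 15, 30, 45)) {
    tr <- generateSpinePhantom(phantomSpecForAngle(ang, seed = 1))$truth
    expect_equal(phiTrue(tr), ang, tolerance = 1e-6)
  }
})

test_that("training patches have the requested counts, labels and contrast", {
  sp <- PhantomSpec(seed = 21)
  ts <- generateTrainingPatches(sp, nPos = 10, nNeg = 20,
                                window = tinyWindow)
  expect_equal(dim(ts$patches), c(tinyWindow, 30))
  expect_equal(sum(ts$labels == 1), 10)
  expect_equal(sum(ts$labels == 0), 20)
  # deterministic for the same spec
  ts2 <- generateTrainingPatches(sp, nPos = 10, nNeg = 20,
                                 window = tinyWindow)
  expect_identical(ts$patches, ts2$patches)
  # vertebra crops are brighter than background crops for fg > bg
  mPos <- mean(ts$patches[, , ts$labels == 1])
  mNeg <- mean(ts$patches[, , ts$labels == 0])
  expect_gt(mPos, mNeg)
  # sampling with replacement covers nPos > nVertebrae without error
  big <- generateTrainingPatches(sp, nPos = 25, nNeg = 1, window = tinyWindow)
  expect_equal(sum(big$labels == 1), 25)
})

test_that("detection recall does greedy one-to-one matching", {
  tr <- generateSpinePhantom(PhantomSpec(seed = 4))$truth
  boxes <- truthBoxes(tr)
  perfect <- data.frame(number = seq_len(nrow(boxes)), top = boxes[, 1],
                        left = boxes[, 2], height = boxes[, 3],
                        width = boxes[, 4], score = 1)
  expect_equal(detectionRecall(perfect, tr, 0.5), 1)
  none <- perfect[0, ]
  expect_equal(detectionRecall(none, tr, 0.5), 0)
  expect_error(detectionRecall(perfect, matrix(numeric(0), 0, 4), 0.5),
               "no boxes")

  # 4 of 5 boxes matched at IoU 0.5: verified against a brute-force
  # assignment oracle over all detection-to-truth injections
  tr5 <- generateSpinePhantom(PhantomSpec(nVertebrae = 5, seed = 4))$truth
  det <- perfect[1:5, ]
  det[, c("top", "left", "height", "width")] <-
    truthBoxes(tr5)[, 1:4]
  det$top[3] <- det$top[3] + 40  # push one detection off its vertebra
  got <- detectionRecall(det, tr5, 0.5)
  expect_equal(got, 0.8)
  bruteBest <- 0
  iou <- outer(seq_len(5), seq_len(5), Vectorize(function(i, j)
    boxIoU(as.numeric(det[i, c("top", "left", "height", "width")]),
           truthBoxes(tr5)[j, ])))
  for (perm in combinat_perms(5)) {
    ok <- sum(iou[cbind(seq_len(5), perm)] >= 0.5)
    bruteBest <- max(bruteBest, ok)
  }
  expect_equal(got, bruteBest / 5)
})

test_that("centroid error is the mean scaled Euclidean distance", {
  a <- rbind(c(1, 2), c(3, 4))
  expect_equal(centroidError(a, a), 0)
  expect_equal(centroidError(rbind(c(3, 4)), rbind(c(0, 0)), 1), 5)
  two <- centroidError(rbind(c(1, 0), c(0, 0)), rbind(c(0, 0), c(0, 1)),
                       spacingMm = 2)
  expect_equal(two, 2)
  expect_error(centroidError(a, a[1, , drop = FALSE]), "length")
})

test_that("ROC points match exhaustive threshold enumeration", {
  expect_error(rocPoints(numeric(0), 1), "non-empty")
  # perfectly separated scores pass through (0, 1)
  sep <- rocPoints(c(5, 6, 7), c(1, 2, 3))
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))
  # identical scores collapse to the diagonal endpoints
  flat <- rocPoints(rep(2, 4), rep(2, 6))
  expect_equal(flat, data.frame(fpr = c(0, 1), tpr = c(0, 1)))
  # monotone from (0,0) to (1,1)
  set.seed(9)
  r <- rocPoints(rnorm(20, 1), rnorm(30))
  expect_equal(r[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r[nrow(r), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  # small mixed example against brute-force thresholds
  sp <- c(0.9, 0.4, 0.4); sn <- c(0.8, 0.4, 0.1)
  got <- rocPoints(sp, sn)
  brute <- unique(do.call(rbind, lapply(sort(unique(c(sp, sn, -Inf, Inf))),
    function(t) data.frame(fpr = mean(sn >= t), tpr = mean(sp >= t)))))
  brute <- brute[order(brute$fpr, brute$tpr), ]
  rownames(brute) <- NULL
  expect_equal(got, brute)
  # cross-check against an independent ROC implementation
  skip_if_not_installed("pROC")
  pr <- pROC::roc(response = c(rep(1, 3), rep(0, 3)),
                  predictor = c(sp, sn), quiet = TRUE)
  prPts <- unique(data.frame(fpr = 1 - pr$specificities,
                             tpr = pr$sensitivities))
  for (k in seq_len(nrow(prPts)))
    expect_true(any(abs(got$fpr - prPts$fpr[k]) < 1e-12 &
                    abs(got$tpr - prPts$tpr[k]) < 1e-12))
})
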