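# 2-D linearly separable toy set: positives shifted along both features.
separableSet <- function(n = 40, gap = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n, mean = 0), n / 2, 2),
             matrix(rnorm(n, mean = gap + 4), n / 2, 2))
  list(X = X, y = c(rep(0L, n / 2), rep(1L, n / 2)))
}

test_that("initial weights form the two-class probability distribution", {
  expect_equal(initWeights(c(0, 0, 1, 1)), rep(0.25, 4))
  w <- initWeights(c(0, 0, 0, 0, 0, 1))
  expect_equal(w, c(rep(0.1, 5), 0.5))
  expect_equal(sum(w), 1)
  set.seed(2)
  y <- rbinom(37, 1, 0.3)
  if (all(y == y[1])) y[1] <- 1 - y[1]
  expect_equal(sum(initWeights(y)), 1)
  expect_error(initWeights(rep(1, 5)), "both classes")
})

test_that("the trained stump matches an exhaustive threshold-scan oracle", {
  s <- separableSet()
  w <- initWeights(s$y)
  stump <- trainWeakLearner(s$X, s$y, w)
  expect_equal(stump$error, 0, tolerance = 1e-12)
  expect_equal(stumpPredict(stump, s$X), s$y)

  # non-separable weighted data: brute-force scan over all candidate
  # thresholds and polarities must reproduce the reported minimal error
  set.seed(8)
  X <- matrix(rnorm(60), 30, 2)
  y <- as.integer(X[, 1] + rnorm(30, sd = 1.2) > 0)
  if (all(y == y[1])) y[1] <- 1 - y[1]
  w <- runif(30); w <- w / sum(w)
  stump <- trainWeakLearner(X, y, w)
  bruteErr <- Inf
  for (j in 1:2) {
    v <- sort(unique(X[, j]))
    cand <- c(v[1] - 1, (head(v, -1) + v[-1]) / 2, v[length(v)] + 1)
    for (thr in cand) for (p in c(1, -1)) {
      h <- as.integer(p * (X[, j] - thr) >= 0)
      bruteErr <- min(bruteErr, sum(w * abs(h - y)))
    }
  }
  expect_equal(stump$error, bruteErr, tolerance = 1e-12)
  hGot <- stumpPredict(stump, X)
  expect_equal(sum(w * abs(hGot - y)), stump$error, tolerance = 1e-12)

  # duplicating every sample with halved weights leaves the stump unchanged
  stump2 <- trainWeakLearner(rbind(X, X), c(y, y), c(w, w) / 2)
  expect_equal(stump2[c("feature", "threshold", "polarity", "error")],
               stump[c("feature", "threshold", "polarity", "error")])

  expect_error(trainWeakLearner(matrix(1, 10, 3), rep(0:1, 5),
                                rep(0.1, 10)), "constant")
})

test_that("weight updates follow the beta rule and renormalize", {
  w <- rep(0.25, 4)
  pred <- c(0, 0, 1, 0)  # last sample (a positive) misclassified
  y <- c(0, 0, 1, 1)
  w2 <- updateWeights(w, pred, y, eps = 0.25)
  # correct samples x 1/3, wrong x 1 before renormalization
  raw <- c(0.25 / 3, 0.25 / 3, 0.25 / 3, 0.25)
  expect_equal(w2, raw / sum(raw))
  expect_equal(sum(w2), 1)
  # misclassified weight strictly gains relative mass for eps < 0.5
  expect_gt(w2[4] / w2[1], w[4] / w[1])
})

test_that("a separable stage meets its targets with few learners", {
  s <- separableSet(n = 60, seed = 3)
  stage <- trainStage(s$X, s$y, tprTarget = 1, fprTarget = 0,
                      maxT = 3L, minT = 1L)
  expect_true(stage$metTargets)
  expect_lte(length(stage$stumps), 3)
  expect_equal(stage$tpr, 1)
  expect_equal(stage$fpr, 0)
  # stage score equals the learner-by-learner additive oracle
  sc <- spinecurve:::stageScore(stage, s$X)
  manual <- numeric(nrow(s$X))
  for (t in seq_along(stage$stumps))
    manual <- manual + stage$alphas[t] *
      as.integer(stage$stumps[[t]]$polarity *
                 (s$X[, stage$stumps[[t]]$feature] -
                  stage$stumps[[t]]$threshold) >= 0)
  expect_equal(sc, manual)
  # the untouched majority-vote cut is half the alpha sum
  expect_equal(stage$defaultThreshold, sum(stage$alphas) / 2)
})

test_that("boosting weights remain a probability distribution each round", {
  set.seed(4)
  X <- matrix(rnorm(200), 100, 2)
  y <- as.integer(X[, 1] + 0.8 * rnorm(100) > 0)
  stage <- suppressWarnings(trainStage(X, y, maxT = 8L, keepWeights = TRUE))
  expect_true(all(stage$weightTrace > 0))
  expect_equal(rowSums(stage$weightTrace),
               rep(1, nrow(stage$weightTrace)), tolerance = 1e-12)
})

test_that("the phantom-trained cascade behaves like a conjunction of stages", {
  model <- phantomCascade()
  expect_s4_class(model, "CascadeModel")
  expect_equal(windowSize(model), tinyWindow)
  rep <- trainingReport(model)
  expect_true(all(rep$tpr >= 0.9))
  expect_true(all(rep$fpr <= 0.03))

  # a clean vertebra crop is accepted, a uniform background patch is not
  ph <- generateSpinePhantom(phantomSpecForAngle(20, seed = 314))
  b <- truthBoxes(ph$truth)[3, ]
  crop <- pixels(ph$image)[b[1]:(b[1] + b[3] - 1), b[2]:(b[2] + b[4] - 1)]
  expect_true(classifyWindow(model, crop)$accepted)
  flat <- matrix(0.25, tinyWindow[1], tinyWindow[2])
  expect_false(classifyWindow(model, flat)$accepted)

  # rejection is monotone in the stage list: truncating the cascade never
  # un-rejects, extending it never un-accepts
  truncated <- model
  truncated@stages <- model@stages[1]
  set.seed(6)
  for (k in 1:5) {
    p <- matrix(runif(prod(tinyWindow), 0, 1), tinyWindow[1], tinyWindow[2])
    if (!classifyWindow(truncated, p)$accepted)
      expect_false(classifyWindow(model, p)$accepted)
  }
})

test_that("cascade training propagates only surviving samples", {
  ts <- phantomTrainingSet(nPosEach = 30, nNegEach = 60, seeds = c(7L, 8L),
                           angles = c(0, 25))
  model <- suppressMessages(trainCascade(
    ts$pos, ts$neg, tinyFeatureConfig(),
    cascadeConfig(nStages = 2L, minWeakPerStage = 3L)))
  rep <- trainingReport(model)
  # cascade FPR on its own pool is bounded by the product of stage FPRs
  fc <- tinyFeatureConfig()
  Xn <- spinecurve:::applyNormalization(
    spinecurve:::featureMatrix(ts$neg, fc),
    list(center = model@normCenter, scale = model@normScale))
  acc <- spinecurve:::cascadeApply(model@stages, Xn)$accepted
  expect_lte(mean(acc), prod(rep$fpr) + 1e-12)
  expect_lte(mean(acc), 0.03^nrow(rep) + 1e-12)
})

test_that("detection finds and numbers the phantom vertebrae in raster order", {
  model <- phantomCascade()
  ph <- generateSpinePhantom(phantomSpecForAngle(15, seed = 777,
                                                 nVertebrae = 5))
  det <- detectVertebrae(model, ph$image, phantomScan())
  expect_equal(nrow(det), 5)
  expect_equal(det$number, 1:5)
  expect_true(all(diff(det$top) > 0))  # numbered top to bottom
  expect_gte(detectionRecall(det, ph$truth, 0.5), 0.8)

  # translating the image moves the detections with it (up to the stride)
  img <- pixels(ph$image)
  shifted <- rbind(matrix(0.25, 12, ncol(img)),
                   img[seq_len(nrow(img) - 12), ])
  det2 <- detectVertebrae(model, SpineImage(shifted), phantomScan())
  expect_equal(nrow(det2), 5)
  expect_lte(max(abs(det2$top - (det$top + 12))), 4)

  expect_error(detectVertebrae(model, matrix(0.5, 10, 10)), "smaller")
})
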