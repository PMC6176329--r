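#' @include features.R
NULL

.EPS_CLAMP <- c(1e-10, 0.5 - 1e-10)

#' Initial boosting weights
#'
#' The initial probability distribution over training samples:
#' `1/(2m)` for each of the `m` negatives and `1/(2l)` for each of the `l`
#' positives, so the weights sum to 1 and the classes carry equal total mass.
#'
#' @param labels integer 0/1 label vector (0 = negative, 1 = positive).
#' @return A weight vector summing to 1.
#' @examples
#' initWeights(c(0, 0, 1, 1))  # all 0.25
#' @export
initWeights <- function(labels) {
  m <- sum(labels == 0); l <- sum(labels == 1)
  if (m < 1 || l < 1) stop("both classes must be present")
  ifelse(labels == 0, 1 / (2 * m), 1 / (2 * l))
}

#' Train the best decision stump under a weight distribution
#'
#' Exhaustively scans every feature, every threshold between distinct sorted
#' values and both polarities for the stump minimising the weighted 0/1 error
#' `sum_i w_i |h(x_i) - y_i|`. Among equal-error stumps the one with the
#' widest value gap at its threshold wins (features are z-scored, so gaps
#' compare across features; a wide-margin stump generalises to windows not in
#' the training set), then lowest feature index and lowest threshold.
#'
#' @param X feature matrix (samples x features).
#' @param labels 0/1 labels.
#' @param weights normalized sample weights.
#' @param exclude feature indices to skip (used to diversify stages when a
#'   single feature separates the classes perfectly).
#' @return A list: `feature`, `threshold`, `polarity` (+1 predicts 1 when
#'   `x >= threshold`; -1 when `x <= threshold`), `error`, `gap`.
#' @export
trainWeakLearner <- function(X, labels, weights, exclude = integer(0)) {
  if (all(apply(X, 2, function(v) max(v) == min(v))))
    stop("all features are constant; no stump can be trained")
  .cpp_best_stump(X, as.integer(labels), weights, as.integer(exclude))
}

#' Predictions of a decision stump
#'
#' @param stump a stump from [trainWeakLearner()].
#' @param X feature matrix.
#' @return Integer 0/1 predictions.
#' @export
stumpPredict <- function(stump, X) {
  v <- X[, stump$feature]
  as.integer(stump$polarity * (v - stump$threshold) >= 0)
}

#' One boosting weight update
#'
#' `w_i <- w_i * beta^(1 - e_i)` with `beta = eps/(1 - eps)` and `e_i = 0`
#' for correctly classified samples, 1 otherwise, then renormalized to a
#' probability distribution. `eps` is clamped away from 0 and 1/2 so
#' `alpha = log(1/beta)` stays finite.
#'
#' @param weights current weights.
#' @param predictions stump 0/1 predictions.
#' @param labels 0/1 labels.
#' @param eps the stump's weighted error.
#' @return Updated, renormalized weights.
#' @export
updateWeights <- function(weights, predictions, labels, eps) {
  eps <- min(max(eps, .EPS_CLAMP[1]), .EPS_CLAMP[2])
  beta <- eps / (1 - eps)
  e <- as.integer(predictions != labels)
  w <- weights * beta^(1 - e)
  w / sum(w)
}

# Additive stage score sum_t alpha_t h_t(x) of a stage's learners.
stageScore <- function(stage, X) {
  s <- numeric(nrow(X))
  for (t in seq_along(stage$stumps))
    s <- s + stage$alphas[t] * stumpPredict(stage$stumps[[t]], X)
  s
}

# Continuous stage margin sum_t alpha_t p_t (x_jt - theta_t): the graded
# analogue of the vote score. Acceptance always uses the discrete vote; this
# margin ranks accepted windows (e.g. for non-maximum suppression), where the
# discrete score ties whenever every stump fires.
stageMargin <- function(stage, X) {
  s <- numeric(nrow(X))
  for (t in seq_along(stage$stumps)) {
    st <- stage$stumps[[t]]
    s <- s + stage$alphas[t] * st$polarity * (X[, st$feature] - st$threshold)
  }
  s
}

# Largest score threshold keeping at least `tprTarget` of positives.
tprThreshold <- function(scoresPos, tprTarget) {
  k <- ceiling(tprTarget * length(scoresPos))
  sort(scoresPos, decreasing = TRUE)[k]
}

#' Train one boosted stage classifier
#'
#' Adds decision stumps (re-selected each round under the boosted weight
#' distribution) until the stage, with its acceptance threshold lowered from
#' the default majority vote `1/2 sum(alpha)` to the largest value keeping
#' TPR >= `tprTarget` on the training positives, also achieves
#' FPR <= `fprTarget` on the training negatives -- or `maxT` learners are
#' reached (then the best stage so far is returned with `metTargets = FALSE`).
#'
#' @param X feature matrix (samples x features).
#' @param labels 0/1 labels.
#' @param tprTarget per-stage true-positive-rate target (default 0.9).
#' @param fprTarget per-stage false-positive-rate target (default 0.03).
#' @param maxT maximum number of weak learners.
#' @param minT minimum number of weak learners: even when the targets are met
#'   immediately, at least this many stumps are boosted so the stage score is
#'   graded rather than a single binary vote (detection scores then rank
#'   candidate windows for non-maximum suppression).
#' @param keepWeights store the per-round weight vectors (for diagnostics).
#' @return A stage: list with `stumps`, `alphas`, `threshold`,
#'   `defaultThreshold` (`1/2 sum(alpha)`), `tpr`, `fpr`, `metTargets`, and
#'   optionally `weightTrace`.
#' @export
trainStage <- function(X, labels, tprTarget = 0.9, fprTarget = 0.03,
                       maxT = 25L, minT = 3L, keepWeights = FALSE) {
  w <- initWeights(labels)
  stage <- list(stumps = list(), alphas = numeric(0))
  trace <- list()
  excluded <- integer(0)
  pos <- labels == 1; neg <- labels == 0
  for (t in seq_len(maxT)) {
    w <- w / sum(w)
    stump <- trainWeakLearner(X, labels, w, exclude = excluded)
    eps <- min(max(stump$error, .EPS_CLAMP[1]), .EPS_CLAMP[2])
    stage$stumps[[t]] <- stump
    stage$alphas[t] <- log((1 - eps) / eps)  # log(1/beta)
    pred <- stumpPredict(stump, X)
    w <- updateWeights(w, pred, labels, stump$error)
    if (keepWeights) trace[[t]] <- w
    # a perfect stump leaves the weights unchanged and would be re-selected
    # verbatim; exclude its feature so later rounds add new evidence
    if (stump$error < 1e-9 && length(excluded) < ncol(X) - 1L)
      excluded <- c(excluded, stump$feature)

    s <- stageScore(stage, X)
    thr <- tprThreshold(s[pos], tprTarget)
    acc <- s >= thr
    tpr <- mean(acc[pos]); fpr <- mean(acc[neg])
    if (t >= minT && tpr >= tprTarget && fpr <= fprTarget) break
  }
  if (!(tpr >= tprTarget && fpr <= fprTarget))
    warning(sprintf("stage targets not met at maxT = %d (TPR %.3f, FPR %.3f)",
                    maxT, tpr, fpr))
  stage$threshold <- thr
  stage$defaultThreshold <- sum(stage$alphas) / 2
  stage$tpr <- tpr; stage$fpr <- fpr
  stage$metTargets <- (tpr >= tprTarget && fpr <= fprTarget)
  if (keepWeights) stage$weightTrace <- do.call(rbind, trace)
  stage
}

#' Cascade training configuration
#'
#' @param nStages maximum number of cascade stages (default 10).
#' @param tprTarget,fprTarget per-stage targets (defaults 0.9 and 0.03).
#' @param maxWeakPerStage weak-learner cap per stage.
#' @param minWeakPerStage weak-learner floor per stage (graded stage scores).
#' @param minNegPerStage refill the negative pool to at least this many hard
#'   negatives before each stage, when a `negSource` is available.
#' @return A named list of cascade hyperparameters.
#' @export
cascadeConfig <- function(nStages = 10L, tprTarget = 0.9, fprTarget = 0.03,
                          maxWeakPerStage = 25L, minWeakPerStage = 3L,
                          minNegPerStage = 100L) {
  list(nStages = as.integer(nStages), tprTarget = tprTarget,
       fprTarget = fprTarget, maxWeakPerStage = as.integer(maxWeakPerStage),
       minWeakPerStage = as.integer(minWeakPerStage),
       minNegPerStage = as.integer(minNegPerStage))
}

# Accept/score all rows of a normalized feature matrix through the stages.
# Returns list(accepted, score, stage): acceptance is the discrete stage vote
# (score >= stage threshold) at every stage; `score` is the final evaluated
# stage's continuous margin (graded, for ranking accepted windows).
cascadeApply <- function(stages, Xn) {
  n <- nrow(Xn)
  accepted <- rep(TRUE, n)
  margin <- rep(NA_real_, n)
  lastStage <- rep(0L, n)
  for (k in seq_along(stages)) {
    idx <- which(accepted)
    if (length(idx) == 0) break
    Xi <- Xn[idx, , drop = FALSE]
    s <- stageScore(stages[[k]], Xi)
    margin[idx] <- stageMargin(stages[[k]], Xi)
    lastStage[idx] <- k
    accepted[idx] <- s >= stages[[k]]$threshold
  }
  list(accepted = accepted, score = margin, stage = lastStage)
}

#' Train a cascade gentle-AdaBoost vertebra detector
#'
#' Stages are trained in sequence from simple to complex: each stage trains
#' on the positives that passed every earlier stage and on the false
#' positives of the cascade so far (negative bootstrapping). When the
#' surviving false positives run low, fresh candidate negatives are drawn
#' from `negSource` and filtered through the current cascade; training stops
#' early when no false positives remain. Feature normalization statistics are
#' fitted on the initial training set and stored with the model.
#'
#' @param posPatches,negPatches patch arrays (`h x w x n`) at the window size.
#' @param fconfig a [featureConfig()]; its window fixes the patch shape.
#' @param config a [cascadeConfig()].
#' @param negSource optional function `function(n)` returning an `h x w x n`
#'   array of fresh background patches for bootstrapping.
#' @return A [CascadeModel-class].
#' @export
trainCascade <- function(posPatches, negPatches, fconfig = featureConfig(),
                         config = cascadeConfig(), negSource = NULL) {
  if (length(dim(posPatches)) != 3 || length(dim(negPatches)) != 3 ||
      dim(posPatches)[3] < 1 || dim(negPatches)[3] < 1)
    stop("patch sets must be non-empty h x w x n arrays")
  pool <- haarPool(fconfig)
  Xpos <- featureMatrix(posPatches, fconfig, pool)
  Xneg <- featureMatrix(negPatches, fconfig, pool)
  norm <- fitFeatureNormalization(rbind(Xpos, Xneg))
  Xpos <- applyNormalization(Xpos, norm)
  Xneg <- applyNormalization(Xneg, norm)

  stages <- list()
  report <- data.frame(tpr = numeric(0), fpr = numeric(0),
                       learners = integer(0), nNeg = integer(0))
  for (k in seq_len(config$nStages)) {
    # replenish hard negatives from the source if the pool ran low
    if (!is.null(negSource) && nrow(Xneg) < config$minNegPerStage) {
      for (batch in 1:20) {
        fresh <- negSource(200L)
        Xf <- applyNormalization(featureMatrix(fresh, fconfig, pool), norm)
        if (length(stages) > 0)
          Xf <- Xf[cascadeApply(stages, Xf)$accepted, , drop = FALSE]
        if (nrow(Xf) > 0) Xneg <- rbind(Xneg, Xf)
        if (nrow(Xneg) >= config$minNegPerStage) break
      }
    }
    if (nrow(Xneg) == 0) {
      message("cascade: no false positives remain; stopping at stage ", k - 1)
      break
    }
    X <- rbind(Xpos, Xneg)
    y <- c(rep(1L, nrow(Xpos)), rep(0L, nrow(Xneg)))
    stage <- trainStage(X, y, config$tprTarget, config$fprTarget,
                        config$maxWeakPerStage, config$minWeakPerStage)
    stages[[k]] <- stage
    report <- rbind(report, data.frame(tpr = stage$tpr, fpr = stage$fpr,
                                       learners = length(stage$stumps),
                                       nNeg = nrow(Xneg)))
    # pass-through semantics: positives surviving this stage, negatives that
    # still fool it
    sPos <- stageScore(stage, Xpos)
    Xpos <- Xpos[sPos >= stage$threshold, , drop = FALSE]
    if (nrow(Xpos) == 0)
      stop("positives exhausted by stage filtering at stage ", k)
    sNeg <- stageScore(stage, Xneg)
    Xneg <- Xneg[sNeg >= stage$threshold, , drop = FALSE]
  }
  new("CascadeModel", window = fconfig$window,
      featureConfig = unclass(fconfig),
      normCenter = norm$center, normScale = norm$scale,
      stages = stages, report = report)
}

#' Classify one window with a cascade model
#'
#' The window is rejected at the first failing stage (the discrete vote of
#' the stage's stumps against the stage threshold); the score is the final
#' evaluated stage's continuous margin, which grades how far the window's
#' stump features sit on the accepting side of their thresholds.
#'
#' @param model a [CascadeModel-class].
#' @param patch numeric matrix at the model's window size.
#' @return A list: `accepted` (logical), `score` (margin), `stage` (index of
#'   the last evaluated stage).
#' @export
classifyWindow <- function(model, patch) {
  cfg <- do.call(featureConfig, model@featureConfig)
  v <- extractFeatures(patch, cfg, model@normCenter, model@normScale)
  res <- cascadeApply(model@stages, matrix(v, 1))
  list(accepted = res$accepted[1], score = res$score[1], stage = res$stage[1])
}

#' Scan configuration for sliding-window detection
#'
#' @param stride scan stride in px (raster order, left-to-right then
#'   top-to-bottom).
#' @param scaleFactor image-pyramid scale factor between levels.
#' @param nScales number of pyramid levels (1 = base scale only).
#' @param nmsIoU detections overlapping a higher-scoring detection by more
#'   than this IoU are suppressed.
#' @return A named list of scan parameters.
#' @export
scanConfig <- function(stride = 8L, scaleFactor = 1.1, nScales = 3L,
                       nmsIoU = 0.3) {
  list(stride = as.integer(stride), scaleFactor = scaleFactor,
       nScales = as.integer(nScales), nmsIoU = nmsIoU)
}

#' Detect vertebrae in an image
#'
#' Slides the model's window in raster order at the configured stride over an
#' image pyramid; windows accepted by every cascade stage are merged by
#' non-maximum suppression (descending score, IoU > `nmsIoU` suppressed) and
#' the survivors are numbered 1..K in raster order of their top-left corner
#' -- superior to inferior for upright slices.
#'
#' @param model a [CascadeModel-class].
#' @param image a [SpineImage-class] (or intensity matrix), at least
#'   window-sized.
#' @param scan a [scanConfig()].
#' @return A data.frame with columns `number`, `top`, `left`, `height`,
#'   `width`, `score` (boxes in original-image pixels, 1-based closed).
#' @export
detectVertebrae <- function(model, image, scan = scanConfig()) {
  m <- if (is(image, "SpineImage")) pixels(image) else image
  win <- model@window
  if (nrow(m) < win[1] || ncol(m) < win[2])
    stop("image (", nrow(m), "x", ncol(m), ") is smaller than the detection ",
         "window (", win[1], "x", win[2], ")")
  cfg <- do.call(featureConfig, model@featureConfig)
  pool <- haarPool(cfg)
  norm <- list(center = model@normCenter, scale = model@normScale)

  hits <- list()
  for (lev in seq_len(scan$nScales)) {
    s <- scan$scaleFactor^(lev - 1)
    sm <- if (s == 1) m else
      resizeMatrix(m, max(win[1], round(nrow(m) / s)),
                   max(win[2], round(ncol(m) / s)))
    if (nrow(sm) < win[1] || ncol(sm) < win[2]) break
    tops <- seq(1L, nrow(sm) - win[1] + 1L, by = scan$stride)
    lefts <- seq(1L, ncol(sm) - win[2] + 1L, by = scan$stride)
    grid <- expand.grid(left = lefts, top = tops)  # raster order
    # batch the windows to bound memory while keeping extraction vectorized
    chunk <- 1000L
    for (start in seq(1L, nrow(grid), by = chunk)) {
      idx <- start:min(start + chunk - 1L, nrow(grid))
      patches <- array(0, dim = c(win[1], win[2], length(idx)))
      for (q in seq_along(idx)) {
        tp <- grid$top[idx[q]]; lf <- grid$left[idx[q]]
        patches[, , q] <- sm[tp:(tp + win[1] - 1L), lf:(lf + win[2] - 1L)]
      }
      Xn <- applyNormalization(featureMatrix(patches, cfg, pool), norm)
      res <- cascadeApply(model@stages, Xn)
      keep <- which(res$accepted)
      if (length(keep) > 0)
        hits[[length(hits) + 1L]] <- data.frame(
          top = round((grid$top[idx[keep]] - 1L) * s) + 1L,
          left = round((grid$left[idx[keep]] - 1L) * s) + 1L,
          height = round(win[1] * s), width = round(win[2] * s),
          score = res$score[keep])
    }
  }
  all <- if (length(hits) > 0) do.call(rbind, hits) else
    data.frame(top = integer(0), left = integer(0), height = integer(0),
               width = integer(0), score = numeric(0))
  det <- nonMaxSuppress(all, scan$nmsIoU)
  det <- refineByVoting(det, all)
  det <- nonMaxSuppress(det, scan$nmsIoU)
  det <- det[order(det$top, det$left), , drop = FALSE]
  rownames(det) <- NULL
  cbind(number = seq_len(nrow(det)), det)
}

# Box voting: each NMS-surviving peak is replaced by the score-weighted
# average of all accepted windows overlapping it by IoU >= voteIoU. The
# accepted windows around one vertebra straddle it roughly symmetrically, so
# voting centres the final box better than any single stride-aligned window.
refineByVoting <- function(det, all, voteIoU = 0.45) {
  if (nrow(det) == 0 || nrow(all) == 0) return(det)
  allBoxes <- as.matrix(all[, c("top", "left", "height", "width")])
  for (i in seq_len(nrow(det))) {
    b <- as.numeric(det[i, c("top", "left", "height", "width")])
    sel <- which(apply(allBoxes, 1, boxIoU, b = b) >= voteIoU)
    if (length(sel) < 2) next
    s <- all$score[sel]
    w <- s - min(s) + 0.1 * (max(s) - min(s)) + 1e-9
    det$top[i] <- round(sum(w * all$top[sel]) / sum(w))
    det$left[i] <- round(sum(w * all$left[sel]) / sum(w))
    det$height[i] <- round(sum(w * all$height[sel]) / sum(w))
    det$width[i] <- round(sum(w * all$width[sel]) / sum(w))
  }
  det
}

# Greedy NMS by descending score.
nonMaxSuppress <- function(det, iouMax) {
  if (nrow(det) <= 1) return(det)
  det <- det[order(-det$score), , drop = FALSE]
  keep <- logical(nrow(det))
  boxes <- as.matrix(det[, c("top", "left", "height", "width")])
  for (i in seq_len(nrow(det))) {
    ok <- TRUE
    if (any(keep)) {
      ious <- apply(boxes[keep, , drop = FALSE], 1, boxIoU, b = boxes[i, ])
      ok <- all(ious <= iouMax)
    }
    keep[i] <- ok
  }
  det[keep, , drop = FALSE]
}
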