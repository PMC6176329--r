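# Shared fixtures: a small canonical window for fast feature/cascade tests,
# and a lazily trained phantom cascade reused across test files.

tinyWindow <- c(24L, 30L)

tinyFeatureConfig <- function() featureConfig(window = tinyWindow)

# Pooled training patches from a few phantoms at varied curvatures.
phantomTrainingSet <- function(nPosEach = 60, nNegEach = 120,
                               seeds = c(101L, 102L, 103L),
                               angles = c(0, 15, 35)) {
  sets <- mapply(function(a, s)
    generateTrainingPatches(phantomSpecForAngle(a, seed = s),
                            nPos = nPosEach, nNeg = nNegEach,
                            window = tinyWindow),
    angles, seeds, SIMPLIFY = FALSE)
  pos <- array(unlist(lapply(sets, function(s) s$patches[, , s$labels == 1])),
               dim = c(tinyWindow, nPosEach * length(sets)))
  neg <- array(unlist(lapply(sets, function(s) s$patches[, , s$labels == 0])),
               dim = c(tinyWindow, nNegEach * length(sets)))
  list(pos = pos, neg = neg)
}

.cascadeCache <- new.env(parent = emptyenv())

# Phantom-trained detector: 3 configured stages, reduced pools; cached for
# the session because several files exercise it.
phantomCascade <- function() {
  if (is.null(.cascadeCache$model)) {
    ts <- phantomTrainingSet()
    .cascadeCache$model <- suppressMessages(trainCascade(
      ts$pos, ts$neg, tinyFeatureConfig(),
      cascadeConfig(nStages = 3L, maxWeakPerStage = 20L,
                    minWeakPerStage = 6L)))
  }
  .cascadeCache$model
}

phantomScan <- function() scanConfig(stride = 4L, nScales = 1L)

# A noisy disk image with truth mask, for level-set convergence checks.
diskImage <- function(n = 150, radius = 30, fg = 0.85, bg = 0.25,
                      noiseSd = 0.04, seed = 5) {
  ctr <- (n + 1) / 2
  rr <- outer(seq_len(n) - ctr, rep(1, n))
  cc <- outer(rep(1, n), seq_len(n) - ctr)
  d <- sqrt(rr^2 + cc^2)
  img <- matrix(bg, n, n)
  img[d <= radius] <- fg
  set.seed(seed)
  img <- pmax(pmin(img + matrix(rnorm(n * n, sd = noiseSd), n, n), 1), 0)
  list(image = img, truth = (d <= radius) + 0, dist = d, radius = radius)
}

# Mean absolute distance of mask boundary pixels to the true circle.
diskBoundaryDistance <- function(mask, dist, radius) {
  n <- nrow(mask)
  er <- rbind(mask[-1, ], 0) & rbind(0, mask[-n, ]) &
    cbind(mask[, -1], 0) & cbind(0, mask[, -n])
  boundary <- mask == 1 & !er
  mean(abs(dist[boundary] - radius))
}

# All permutations of 1..n (tiny n), for brute-force matching oracles.
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}
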