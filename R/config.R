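#' @include AllClasses.R
NULL

#' Pipeline configuration with validated defaults
#'
#' Central defaults for every stage of the pipeline: detector window 90 x 80
#' px, per-stage TPR target 0.9 and FPR target 0.03 over at most 10 cascade
#' stages; DRLSE weights mu = 0.04, lambda = 5, alpha = 1.5, Dirac width
#' epsilon = 1.5 and Gaussian scale sigma = 1.5 over 200 iterations; HOG cell
#' 8 px; plus the scan, NMS, CLAHE, ROI-padding and curve-degree parameters.
#' Unknown keys are rejected, values are validated.
#'
#' @param ... overrides of the defaults listed above (see
#'   [featureConfig()], [cascadeConfig()], [scanConfig()], [drlseParams()]).
#' @return A named list (class `"pipelineConfig"`).
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    version = "1.0",
    window = c(90L, 80L),
    tprTarget = 0.9, fprTarget = 0.03, nStages = 10L,
    maxWeakPerStage = 25L, minNegPerStage = 100L,
    haarScales = c(1 / 2, 1 / 3, 1 / 4), haarStrideFrac = 1 / 4,
    lbpGrid = c(4L, 4L), hogCell = 8L, hogBins = 9L,
    stride = 8L, scaleFactor = 1.1, nScales = 3L, nmsIoU = 0.3,
    mu = 0.04, lambda = 5, alpha = 1.5, epsilon = 1.5, sigma = 1.5,
    dt = 3, c0 = 2, iterations = 200L, roiPad = 0.2,
    claheClip = 0.01, claheTiles = c(8L, 8L),
    degree = NULL, flipOrder = FALSE)
  over <- list(...)
  if (length(over) > 0 &&
      (is.null(names(over)) || any(names(over) == "")))
    stop("all configuration overrides must be named")
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(over)] <- over
  validatePipelineConfig(cfg)
  structure(cfg, class = "pipelineConfig")
}

validatePipelineConfig <- function(cfg) {
  stopifnot(cfg$tprTarget > 0, cfg$tprTarget <= 1,
            cfg$fprTarget > 0, cfg$fprTarget < 1,
            cfg$nStages >= 1, cfg$stride >= 1, cfg$nScales >= 1,
            cfg$scaleFactor >= 1, cfg$nmsIoU > 0, cfg$nmsIoU < 1,
            cfg$iterations >= 1, cfg$roiPad >= 0,
            cfg$claheClip > 0, cfg$claheClip <= 1)
  # reuse the component validators
  featureConfig(cfg$window, cfg$haarScales, cfg$haarStrideFrac,
                cfg$lbpGrid, cfg$hogCell, cfg$hogBins)
  drlseParams(cfg$mu, cfg$lambda, cfg$alpha, cfg$epsilon, cfg$sigma,
              cfg$dt, cfg$c0)
  invisible(cfg)
}

featureConfigOf <- function(cfg)
  featureConfig(cfg$window, cfg$haarScales, cfg$haarStrideFrac,
                cfg$lbpGrid, cfg$hogCell, cfg$hogBins)

cascadeConfigOf <- function(cfg)
  cascadeConfig(cfg$nStages, cfg$tprTarget, cfg$fprTarget,
                cfg$maxWeakPerStage, cfg$minNegPerStage)

scanConfigOf <- function(cfg)
  scanConfig(cfg$stride, cfg$scaleFactor, cfg$nScales, cfg$nmsIoU)

drlseParamsOf <- function(cfg)
  drlseParams(cfg$mu, cfg$lambda, cfg$alpha, cfg$epsilon, cfg$sigma,
              cfg$dt, cfg$c0)

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file with configuration keys; unknown keys are rejected.
#' @return `readPipelineConfig`: a validated config; `writePipelineConfig`:
#'   `path` invisibly.
#' @export
readPipelineConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  intKeys <- c("window", "nStages", "maxWeakPerStage", "minNegPerStage",
               "lbpGrid", "hogCell", "hogBins", "stride", "nScales",
               "iterations", "claheTiles")
  for (k in intersect(intKeys, names(doc))) doc[[k]] <- as.integer(doc[[k]])
  do.call(pipelineConfig, doc)
}

#' @rdname readPipelineConfig
#' @param config a `pipelineConfig` to write.
#' @export
writePipelineConfig <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config), precision = 15), path)
  invisible(path)
}
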