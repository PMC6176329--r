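#' @include config.R
NULL

#' Run the full recognition pipeline on one image
#'
#' detect -> segment -> analyze: sliding-window cascade detection, per-box
#' DRLSE segmentation, centroid extraction, curve fitting, tangent-angle
#' measurement and diagnosis. One structured log line per stage. With an
#' `outDir`, the detections CSV, mask PNGs, centroids CSV and the report are
#' written alongside each other. The input image is never modified.
#'
#' @param image a [SpineImage-class], or a path readable by
#'   [readImagePlane()].
#' @param model a [CascadeModel-class], or a path readable by
#'   [readCascadeModel()].
#' @param view `"coronal"` or `"sagittal"`.
#' @param region spine region (required for sagittal).
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory for artifacts.
#' @return A list: `report` ([CurvatureReport-class]), `detections`,
#'   `masks`, `centroids`, `curve`.
#' @export
runSpinePipeline <- function(image, model, view, region = NULL,
                             config = pipelineConfig(), outDir = NULL) {
  if (is.character(image)) image <- readImagePlane(image, view = view)
  if (is.character(model)) model <- readCascadeModel(model)

  t0 <- proc.time()[3]
  det <- detectVertebrae(model, image, scanConfigOf(config))
  message(sprintf("[detect] %d detection(s) in %.1fs", nrow(det),
                  proc.time()[3] - t0))
  if (nrow(det) < 3)
    stop("pipeline aborted: fewer than 3 vertebrae detected (",
         nrow(det), ")")

  t0 <- proc.time()[3]
  masks <- segmentVertebrae(image, det, drlseParamsOf(config),
                            nIter = config$iterations, pad = config$roiPad)
  nEmpty <- sum(vapply(masks, function(m) sum(m@mask) == 0, TRUE))
  message(sprintf("[segment] %d mask(s), %d empty, in %.1fs",
                  length(masks), nEmpty, proc.time()[3] - t0))
  masks <- Filter(function(m) sum(m@mask) > 0, masks)

  report <- analyzeSpine(masks, view = view, region = region,
                         degree = config$degree,
                         flipOrder = isTRUE(config$flipOrder))
  message(sprintf("[analyze] phi = %.2f deg -> %s", report@phi,
                  report@diagnosisLabel))

  cent <- t(vapply(masks, extractCentroid, c(row = 0, col = 0)))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeDetections(det, file.path(outDir, "detections.csv"))
    writeMasks(masks, dim(pixels(image)), file.path(outDir, "masks"))
    writeCentroids(cent, file.path(outDir, "centroids.csv"))
    writeCurvatureReport(report, file.path(outDir, "report.yaml"))
  }
  list(report = report, detections = det, masks = masks,
       centroids = cent, curve = fitSpineCurve(cent, config$degree))
}
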