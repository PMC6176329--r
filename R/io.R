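#' @include AllClasses.R
NULL

#' Read a 2-D grayscale image as a SpineImage
#'
#' PNG and TIFF are supported; intensities are rescaled to `[0, 1]` and
#' multi-channel images are averaged to one gray channel. Pixel spacing is
#' not carried by these formats, so it defaults to 1 mm/px with a message
#' unless supplied.
#'
#' @param path file path (.png, .tif, .tiff).
#' @param view view label to attach.
#' @param spacing pixel spacing in mm/px; `NULL` logs a warning and uses 1.
#' @return A [SpineImage-class].
#' @export
readImagePlane <- function(path, view = "unknown", spacing = NULL) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext,
         "': PNG and TIFF grayscale images are supported"))
  if (length(dim(m)) == 3) m <- apply(m[, , 1:min(3, dim(m)[3]), drop = FALSE],
                                      c(1, 2), mean)
  if (is.null(spacing)) {
    message("no pixel spacing available for ", basename(path),
            "; assuming 1 mm/px")
    spacing <- 1
  }
  SpineImage(clamp01(m), view = view, spacing = spacing)
}

#' Write a SpineImage (or matrix) as an 8-bit PNG
#'
#' @param image a [SpineImage-class] or `[0, 1]` matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImagePlane <- function(image, path) {
  m <- if (is(image, "SpineImage")) pixels(image) else image
  png::writePNG(m, path)
  invisible(path)
}

#' Write / read a detections table as CSV
#'
#' Columns: `number`, `top`, `left`, `height`, `width`, `score`.
#'
#' @param detections detections data.frame from [detectVertebrae()].
#' @param path CSV path.
#' @return `writeDetections`: `path` invisibly; `readDetections`: the
#'   data.frame.
#' @export
writeDetections <- function(detections, path) {
  write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) {
  det <- read.csv(path)
  need <- c("number", "top", "left", "height", "width", "score")
  if (!all(need %in% names(det)))
    stop("detections CSV must have columns: ", paste(need, collapse = ", "))
  det[, need]
}

#' Write / read centroids as CSV
#'
#' Columns: `number`, `row`, `col`.
#'
#' @param centroids matrix or data.frame with centroid rows/cols; row order
#'   is the vertebra numbering.
#' @param path CSV path.
#' @return `writeCentroids`: `path` invisibly; `readCentroids`: a data.frame.
#' @export
writeCentroids <- function(centroids, path) {
  centroids <- rbind(centroids)
  df <- data.frame(number = seq_len(nrow(centroids)),
                   row = centroids[, 1], col = centroids[, 2])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCentroids
#' @export
readCentroids <- function(path) read.csv(path)[, c("number", "row", "col")]

#' Write vertebra masks as PNGs
#'
#' One 0/255 PNG per vertebra (`mask_<number>.png`, full image frame) plus a
#' combined labelled mask (`labels.png`) whose pixel value encodes the
#' detection number (scaled by 1/255).
#'
#' @param masks list of [VertebraMask-class].
#' @param imageShape `c(rows, cols)` of the source image frame.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
writeMasks <- function(masks, imageShape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- matrix(0, imageShape[1], imageShape[2])
  for (mk in masks) {
    full <- matrix(0, imageShape[1], imageShape[2])
    rows <- mk@offset[1]:(mk@offset[1] + nrow(mk@mask) - 1)
    cols <- mk@offset[2]:(mk@offset[2] + ncol(mk@mask) - 1)
    full[rows, cols] <- mk@mask
    lab[rows, cols][mk@mask == 1] <- mk@number / 255
    png::writePNG(full, file.path(dir, sprintf("mask_%02d.png", mk@number)))
  }
  png::writePNG(lab, file.path(dir, "labels.png"))
  invisible(dir)
}

#' Serialize / load a cascade model
#'
#' A single versioned JSON document holding the window geometry, descriptor
#' configuration, normalization statistics and per-stage stump lists; the
#' round trip is lossless: doubles are encoded as full-precision
#' (`%.17g`) strings, which survive the JSON layer bit-exactly.
#'
#' @param model a [CascadeModel-class].
#' @param path model file path.
#' @return `writeCascadeModel`: `path` invisibly; `readCascadeModel`: the
#'   model.
#' @export
writeCascadeModel <- function(model, path) {
  enc <- function(x) sprintf("%.17g", x)
  fc <- model@featureConfig
  fc$haarScales <- enc(fc$haarScales)
  fc$haarStrideFrac <- enc(fc$haarStrideFrac)
  doc <- list(
    format = "spinecurve-cascade", version = model@version,
    window = model@window, featureConfig = fc,
    normCenter = enc(model@normCenter), normScale = enc(model@normScale),
    stages = lapply(model@stages, function(st) list(
      stumps = lapply(st$stumps, function(s)
        list(feature = s$feature, threshold = enc(s$threshold),
             polarity = s$polarity, error = enc(s$error))),
      alphas = enc(st$alphas), threshold = enc(st$threshold),
      defaultThreshold = enc(st$defaultThreshold),
      tpr = st$tpr, fpr = st$fpr, metTargets = st$metTargets)),
    report = model@report)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCascadeModel
#' @export
readCascadeModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "spinecurve-cascade"))
    stop("not a spinecurve cascade model file: ", path)
  fc <- doc$featureConfig
  fc$window <- as.integer(fc$window)
  fc$lbpGrid <- as.integer(fc$lbpGrid)
  fc$haarScales <- as.numeric(fc$haarScales)
  fc$haarStrideFrac <- as.numeric(fc$haarStrideFrac)
  stages <- lapply(doc$stages, function(st) {
    st$stumps <- lapply(st$stumps, function(s) {
      s$feature <- as.integer(s$feature)
      s$threshold <- as.numeric(s$threshold)
      s$error <- as.numeric(s$error)
      s
    })
    st$alphas <- as.numeric(st$alphas)
    st$threshold <- as.numeric(st$threshold)
    st$defaultThreshold <- as.numeric(st$defaultThreshold)
    st
  })
  report <- if (length(doc$report) > 0) do.call(rbind, lapply(doc$report,
    function(r) as.data.frame(r))) else
    data.frame(tpr = numeric(0), fpr = numeric(0),
               learners = integer(0), nNeg = integer(0))
  new("CascadeModel", window = as.integer(doc$window), featureConfig = fc,
      normCenter = as.numeric(doc$normCenter),
      normScale = as.numeric(doc$normScale),
      stages = stages, report = report,
      version = as.character(doc$version))
}

#' Write / read a curvature report as structured text (YAML)
#'
#' @param report a [CurvatureReport-class].
#' @param path output path.
#' @return `writeCurvatureReport`: `path` invisibly; `readCurvatureReport`:
#'   the report.
#' @export
writeCurvatureReport <- function(report, path) {
  doc <- list(phi_degrees = report@phi, view = report@view,
              region = report@region, diagnosis = report@diagnosisLabel,
              rule = report@rule, r_squared = report@rSquared,
              rmse = report@rmse, n_centroids = report@nCentroids)
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' @rdname writeCurvatureReport
#' @export
readCurvatureReport <- function(path) {
  doc <- yaml::read_yaml(path)
  new("CurvatureReport", phi = doc$phi_degrees, view = doc$view,
      region = doc$region, diagnosisLabel = doc$diagnosis, rule = doc$rule,
      rSquared = if (is.null(doc$r_squared)) NA_real_ else doc$r_squared,
      rmse = if (is.null(doc$rmse)) NA_real_ else doc$rmse,
      nCentroids = if (is.null(doc$n_centroids)) NA_integer_ else
        as.integer(doc$n_centroids))
}
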