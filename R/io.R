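#' Read and write YOLO-format label files
#'
#' One row per box: `class cx cy w h [confidence]`, all coordinates
#' normalized to \[0, 1\] by the image size. Writing uses fixed 6-decimal
#' formatting, so a write/read round trip is lossless to about 1e-5 px at
#' the 960-px scale.
#'
#' @param path label file path.
#' @param imageSize image size in pixels: a scalar (square) or `c(W, H)`.
#' @return `readYoloLabels`: a box data.frame (see [boundingBoxes()]).
#' @export
readYoloLabels <- function(path, imageSize) {
  sz <- rep_len(imageSize, 2)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(boundingBoxes())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (!length(v) %in% c(5L, 6L) || any(is.na(v)))
      stop("malformed YOLO row at line ", i, " of ", path)
    if (any(v[2:5] < 0) || any(v[2:5] > 1))
      stop("coordinates not normalized to [0,1] at line ", i, " of ", path)
    v
  })
  m <- do.call(rbind, rows)
  boundingBoxes(cx = m[, 2] * sz[1], cy = m[, 3] * sz[2],
                w = m[, 4] * sz[1], h = m[, 5] * sz[2],
                confidence = if (ncol(m) == 6L) m[, 6] else rep(1, nrow(m)),
                class_id = as.integer(m[, 1]))
}

#' @rdname readYoloLabels
#' @param boxes box data.frame.
#' @param writeConfidence append the confidence as a 6th column.
#' @export
writeYoloLabels <- function(boxes, path, imageSize, writeConfidence = TRUE) {
  assertBoxes(boxes)
  sz <- rep_len(imageSize, 2)
  lines <- character(nrow(boxes))
  cls <- if ("class_id" %in% names(boxes)) boxes$class_id else
    rep(0L, nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    base <- sprintf("%d %.6f %.6f %.6f %.6f", cls[i],
                    boxes$cx[i] / sz[1], boxes$cy[i] / sz[2],
                    boxes$w[i] / sz[1], boxes$h[i] / sz[2])
    lines[i] <- if (writeConfidence)
      paste0(base, sprintf(" %.6f", boxes$confidence[i])) else base
  }
  writeLines(lines, path)
  invisible(path)
}

.posesToKeypointDf <- function(poses, image = "") {
  if (!length(poses))
    return(data.frame(image = character(), particle_id = character(),
                      point = character(), x_px = numeric(),
                      y_px = numeric(), confidence = numeric()))
  do.call(rbind, lapply(poses, function(p) {
    data.frame(image = image, particle_id = p@particleId,
               point = p@points$point, x_px = p@points$x,
               y_px = p@points$y, confidence = p@points$confidence)
  }))
}

#' Read and write keypoint CSV files
#'
#' Dialect: columns `image, particle_id, point, x_px, y_px, confidence`,
#' one row per keypoint; missing keypoints have empty/NA coordinates and
#' confidence 0. The same dialect is used for ground truth and predictions.
#'
#' @param path CSV path.
#' @param schema a [DeviceSchema-class] or a built-in schema name; rows with
#'   point names outside the schema raise an error.
#' @return `readKeypointCsv`: named list of [KeypointPose-class] (names
#'   `image/particle_id`).
#' @export
readKeypointCsv <- function(path, schema = hingeSchema()) {
  if (is.character(schema)) schema <- getSchema(schema)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "particle_id", "point", "x_px", "y_px", "confidence")
  if (!all(need %in% names(df)))
    stop("keypoint CSV needs columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$point), schema@keypointNames)
  if (length(bad))
    stop("unknown point name(s) for schema '", schema@name, "': ",
         paste(bad, collapse = ", "))
  if (!nrow(df)) return(list())
  key <- paste(df$image, df$particle_id, sep = "/")
  out <- lapply(split(df, factor(key, levels = unique(key))), function(d) {
    keypointPose(d$particle_id[1], schema, data.frame(
      point = d$point, x = d$x_px, y = d$y_px,
      confidence = ifelse(is.finite(d$x_px) & is.finite(d$y_px),
                          d$confidence, 0)))
  })
  out
}

#' @rdname readKeypointCsv
#' @param poses list of [KeypointPose-class].
#' @param image image name(s) recorded in the `image` column (recycled).
#' @export
writeKeypointCsv <- function(poses, path, image = "") {
  image <- rep_len(image, max(1L, length(poses)))
  df <- if (length(poses))
    do.call(rbind, lapply(seq_along(poses), function(i)
      .posesToKeypointDf(poses[i], image = image[i])))
  else .posesToKeypointDf(list())
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write grayscale micrographs (PNG or TIFF)
#'
#' Multi-channel images are averaged to one grayscale channel; intensities
#' are clipped to \[0, 1\] on write.
#'
#' @param path image path; format chosen by extension (`.png`, `.tif(f)`).
#' @param nmPerPx calibration attached to the returned [Micrograph-class].
#' @export
readMicrograph <- function(path, nmPerPx = 1.4) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF files")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:min(3, dim(arr)[3]),
                                               drop = FALSE], c(1, 2), mean)
  Micrograph(arr, nmPerPx = nmPerPx)
}

#' @rdname readMicrograph
#' @param m a [Micrograph-class].
#' @export
writeMicrograph <- function(m, path) {
  png::writePNG(pmin(pmax(m@pixels, 0), 1), path)
  invisible(path)
}

#' Default run configuration for [runPipeline()]
#'
#' A nested list mirroring the pipeline stages. Any subset can be
#' overridden via [readRunConfig()] (YAML) or by modifying the list.
#'
#' @return the default configuration list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1,
    nmPerPx = 1.4,
    schema = "hinge",
    simulation = list(enabled = TRUE, nImages = 20),
    input = list(imageDir = NULL, pattern = "\\.png$"),
    detection = list(confThreshold = 0.47, iouThreshold = 0.3,
                     bbfAspect = 1.5, boxSize = 50),
    pose = list(confThreshold = 0.92, cropSize = 200),
    mechanics = list(binWidth = 5, kT = 1),
    outDir = NULL
  )
}

#' Read a YAML run configuration
#'
#' Values present in the file override [defaultRunConfig()]; everything
#' else keeps its default.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  .mergeConfig(defaultRunConfig(), user)
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}
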