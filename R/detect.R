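#' Parameters of the classical particle detector
#'
#' The classical reference backend finds bright connected components and
#' scores each candidate by how well it matches an isolated two-arm
#' particle. Defaults are calibrated to the simulator's default geometry
#' (70 nm arms, 10 nm width, 1.4 nm/px, i.e. 50 x 7.1 px arms).
#'
#' @param armLengthPx,armWidthPx expected arm length/width in pixels.
#' @param blurSigma Gaussian smoothing sd before thresholding (px).
#' @param openRadius radius of the morphological opening/closing brush (px).
#' @param expectedArea expected particle area in px^2; default
#'   `2 * armLengthPx * armWidthPx` (two arms).
#' @param areaMin,areaMax component area bounds in px^2; defaults
#'   0.25 and 4 times `expectedArea`.
#' @param areaTol relative width of the area score (see Details).
#' @param coverageSlack extra tolerance (px) added to the arm half-width
#'   when computing the two-segment coverage score.
#' @param maxForegroundFrac if thresholding marks more than this fraction of
#'   the image as foreground, the image is treated as particle-free (a
#'   threshold on near-uniform background splits noise, not particles).
#'
#' @details The candidate confidence is a documented monotone score in
#' \[0, 1\]: `sqrt(areaScore * shapeScore)` where
#' `areaScore = exp(-((A/expectedArea - 1)/areaTol)^2)` measures closeness
#' of the component area to the expected two-arm area, and `shapeScore` is
#' the fraction of component pixels lying within the best two-segment
#' (vertex + two arms) fit of the component skeleton. Rods (no skeleton
#' branch point) are scored against their single best segment, so their
#' shape score is high but their area score is low; aggregates score low on
#' both.
#' @return a parameter list for [classicalDetect()].
#' @export
detectionParams <- function(armLengthPx = 50, armWidthPx = 50 / 7,
                            blurSigma = 1.5, openRadius = 2,
                            expectedArea = 2 * armLengthPx * armWidthPx,
                            areaMin = 0.25 * expectedArea,
                            areaMax = 4 * expectedArea,
                            areaTol = 0.4, coverageSlack = 2,
                            maxForegroundFrac = 0.3) {
  list(armLengthPx = armLengthPx, armWidthPx = armWidthPx,
       blurSigma = blurSigma, openRadius = openRadius,
       expectedArea = expectedArea, areaMin = areaMin, areaMax = areaMax,
       areaTol = areaTol, coverageSlack = coverageSlack,
       maxForegroundFrac = maxForegroundFrac)
}

#' Classical reference particle detector
#'
#' Normalizes intensity, smooths, thresholds (Otsu), cleans the binary map
#' by morphological opening and closing, extracts 8-connected components
#' within the area bounds and proposes one box per component, sorted by
#' descending confidence (see [detectionParams()] for the score).
#'
#' Interior components that pass the two-arm skeleton analysis are reported
#' as square boxes (side = the larger tight-extent dimension, centred on the
#' component centroid), emulating the square-box annotation convention the
#' detector stands in for; components touching the image border, and
#' components without a two-arm structure, keep their tight extent — so
#' boundary-truncated particles carry a high aspect ratio and are later
#' removed by [bbfFilter()].
#'
#' @param m a [Micrograph-class] (or numeric matrix).
#' @param params see [detectionParams()].
#' @return box data.frame (see [boundingBoxes()]); empty on a blank image.
#' @export
classicalDetect <- function(m, params = detectionParams()) {
  pixels <- if (is(m, "Micrograph")) m@pixels else m
  if (isTRUE(attr(params, "invert")) ) pixels <- 1 - pixels
  norm <- .normalizeImage(pixels)
  if (is.null(norm)) return(boundingBoxes())
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(norm),
                                          sigma = params$blurSigma))
  bin <- sm > .otsu(sm)
  if (mean(bin) > params$maxForegroundFrac) return(boundingBoxes())
  brush <- EBImage::makeBrush(2L * as.integer(params$openRadius) + 1L, "disc")
  bin <- EBImage::imageData(EBImage::closing(
    EBImage::opening(EBImage::Image(bin * 1), brush), brush)) > 0.5
  labels <- .label8(bin)
  nComp <- max(labels)
  if (nComp == 0) return(boundingBoxes())
  nr <- nrow(bin); nc <- ncol(bin)
  idx <- which(labels > 0)
  lab <- labels[idx]
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  out <- list()
  for (k in seq_len(nComp)) {
    sel <- lab == k
    area <- sum(sel)
    if (area < params$areaMin || area > params$areaMax) next
    r <- row[sel]; cc <- col[sel]
    x0 <- min(cc) - 1; x1 <- max(cc); y0 <- min(r) - 1; y1 <- max(r)
    wT <- x1 - x0; hT <- y1 - y0
    cx <- mean(cc - 0.5); cy <- mean(r - 0.5)
    border <- x0 <= 0 || y0 <= 0 || x1 >= nc || y1 >= nr
    # analyse the component in a padded local patch
    pr <- max(1L, min(r) - 2L):min(nr, max(r) + 2L)
    pc <- max(1L, min(cc) - 2L):min(nc, max(cc) + 2L)
    patch <- labels[pr, pc] == k
    ana <- .analyzeTwoArm(patch,
                          minBranchLen = 0.25 * params$armLengthPx,
                          excludeRadius = params$armWidthPx)
    halfW <- params$armWidthPx / 2 + params$coverageSlack
    if (isTRUE(ana$ok)) {
      segs <- list(list(ana$vertex, ana$tips[[1]]),
                   list(ana$vertex, ana$tips[[2]]))
      shape <- .segmentCoverage(patch, segs, halfW)
      twoArm <- TRUE
    } else if (isTRUE(ana$rod)) {
      shape <- .segmentCoverage(patch, list(ana$ends), halfW)
      twoArm <- FALSE
    } else {
      shape <- 0.1
      twoArm <- FALSE
    }
    areaScore <- exp(-((area / params$expectedArea - 1) / params$areaTol)^2)
    conf <- min(1, max(0, sqrt(areaScore * shape)))
    if (twoArm && !border) {
      side <- max(wT, hT)
      out[[length(out) + 1L]] <- c(cx, cy, side, side, conf)
    } else {
      out[[length(out) + 1L]] <- c(cx, cy, wT, hT, conf)
    }
  }
  if (!length(out)) return(boundingBoxes())
  b <- do.call(rbind, out)
  boxes <- boundingBoxes(cx = b[, 1], cy = b[, 2], w = b[, 3], h = b[, 4],
                         confidence = b[, 5])
  boxes[order(-boxes$confidence, boxes$cx, boxes$cy), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-confidence box and discards remaining boxes
#' whose IoU with a kept box exceeds `iouThreshold`. Ties are broken by
#' confidence, then smaller `cx`, then smaller `cy`, for determinism.
#'
#' @param boxes box data.frame.
#' @param iouThreshold IoU above which a box is suppressed (default 0.3).
#' @return the surviving boxes, ordered by descending confidence.
#' @export
nms <- function(boxes, iouThreshold = 0.3) {
  assertBoxes(boxes)
  stopifnot(iouThreshold >= 0, iouThreshold <= 1)
  if (!nrow(boxes)) return(boxes)
  ord <- order(-boxes$confidence, boxes$cx, boxes$cy)
  boxes <- boxes[ord, , drop = FALSE]
  keep <- logical(nrow(boxes))
  active <- rep(TRUE, nrow(boxes))
  M <- iouMatrix(boxes, boxes)
  for (i in seq_len(nrow(boxes))) {
    if (!active[i]) next
    keep[i] <- TRUE
    sup <- which(active & M[i, ] > iouThreshold)
    active[sup] <- FALSE
  }
  out <- boxes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bounding-box-size filter (BBF)
#'
#' Removes all boxes with aspect ratio (max(w,h)/min(w,h)) greater than
#' `maxAspect`, then re-defines the width and height of the survivors to
#' `squareSize` pixels at unchanged centres. Order and confidences are
#' preserved. High-aspect boxes are dominated by boundary-truncated
#' particles and clutter, so this filter trades a small number of true
#' positives for a large false-positive reduction.
#'
#' @param boxes box data.frame.
#' @param maxAspect aspect-ratio cutoff (default 1.5).
#' @param squareSize re-squared box side in pixels (default 50).
#' @return filtered, re-squared boxes.
#' @export
bbfFilter <- function(boxes, maxAspect = 1.5, squareSize = 50) {
  assertBoxes(boxes)
  stopifnot(squareSize > 0)
  if (!nrow(boxes)) return(boxes)
  keep <- boxAspect(boxes) <= maxAspect
  out <- boxes[keep, , drop = FALSE]
  out$w <- squareSize
  out$h <- squareSize
  rownames(out) <- NULL
  out
}

#' Filter boxes by confidence
#'
#' Retains boxes with confidence greater than or equal to `threshold`
#' (inclusive comparison), preserving order.
#'
#' @param boxes box data.frame.
#' @param threshold confidence cutoff in \[0, 1\] (default 0.47).
#' @return the retained boxes.
#' @export
filterByConfidence <- function(boxes, threshold = 0.47) {
  assertBoxes(boxes)
  stopifnot(threshold >= 0, threshold <= 1)
  out <- boxes[boxes$confidence >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Crop particle images from a micrograph
#'
#' Each box region (clipped to the image) is resampled to
#' `outSize` x `outSize` pixels. The returned provenance records the affine
#' map between crop and micrograph coordinates so keypoints can be mapped
#' back exactly: `crop = (micrograph - origin) * scale` per axis.
#'
#' @param m a [Micrograph-class].
#' @param boxes box data.frame.
#' @param outSize crop side in pixels (default 200).
#' @return list of crops, each a list with `image` (matrix) and `provenance`
#'   (list `x0, y0, scaleX, scaleY, box, clipped, index`). Boxes whose
#'   clipped region has zero area are skipped with a warning.
#' @export
cropParticles <- function(m, boxes, outSize = 200) {
  assertBoxes(boxes)
  pixels <- if (is(m, "Micrograph")) m@pixels else m
  W <- ncol(pixels); H <- nrow(pixels)
  crops <- list()
  for (i in seq_len(nrow(boxes))) {
    x0 <- max(0L, as.integer(floor(boxes$cx[i] - boxes$w[i] / 2)))
    x1 <- min(W, as.integer(ceiling(boxes$cx[i] + boxes$w[i] / 2)))
    y0 <- max(0L, as.integer(floor(boxes$cy[i] - boxes$h[i] / 2)))
    y1 <- min(H, as.integer(ceiling(boxes$cy[i] + boxes$h[i] / 2)))
    if (x1 - x0 <= 0 || y1 - y0 <= 0) {
      warning("box ", i, " has zero area after clipping; skipped")
      next
    }
    sub <- pixels[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
    img <- EBImage::imageData(EBImage::resize(EBImage::Image(sub),
                                              w = outSize, h = outSize))
    clipped <- (x1 - x0) != (y1 - y0) ||
      x0 > boxes$cx[i] - boxes$w[i] / 2 + 1 ||
      x1 < boxes$cx[i] + boxes$w[i] / 2 - 1
    crops[[length(crops) + 1L]] <- list(
      image = img,
      provenance = list(x0 = x0, y0 = y0,
                        scaleX = outSize / (x1 - x0),
                        scaleY = outSize / (y1 - y0),
                        box = boxes[i, , drop = FALSE],
                        clipped = clipped, index = i))
  }
  crops
}
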