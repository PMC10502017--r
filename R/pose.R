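#' Parameters of the classical pose estimator
#'
#' @param blurSigma Gaussian smoothing sd (px) applied to the crop before
#'   thresholding; upsampled crops have blocky edges that would otherwise
#'   roughen the skeleton.
#' @param closeRadius radius (px) of the morphological closing applied to
#'   the binary map; bridges the thin pinch that can appear at the dim
#'   vertex corner.
#' @param minBranchLen minimum skeleton branch length (px, in the crop
#'   frame) for a branch to count as an arm; shorter spurs are ignored.
#' @param confScale scale (px) of the residual term of the keypoint
#'   confidence, `exp(-(rms / confScale)^2)`, where `rms` is the
#'   perpendicular RMS residual of the arm's line fit.
#' @param coverageFloor coverage term of the confidence:
#'   `min(1, (coverage / coverageFloor)^4)`, where `coverage` is the
#'   fraction of significant foreground pixels explained by the fitted
#'   two-segment model. A fit that explains only part of the particle
#'   (e.g. one arm of a split mask) is down-weighted sharply.
#' @param keepFloor inlier term of the confidence,
#'   `min(1, keepFrac / keepFloor)` with `keepFrac` the fraction of
#'   skeleton pixels kept by the outlier-trimmed line fit.
#' @param minForeground minimum number of foreground pixels for a crop to be
#'   considered non-blank.
#' @param maxForegroundFrac foreground fraction above which the threshold is
#'   considered to have split background noise (blank crop).
#' @param minBimodality minimum Otsu between-class variance fraction
#'   (sigma_between^2 / sigma_total^2) for the crop to count as containing a
#'   particle; thresholding pure background noise scores well below
#'   thresholding a bright particle on stain.
#' @return a parameter list for [classicalPose()].
#' @export
poseParams <- function(blurSigma = 3, closeRadius = 4, minBranchLen = 25,
                       confScale = 20, coverageFloor = 0.9,
                       keepFloor = 0.9, minForeground = 60,
                       maxForegroundFrac = 0.6, minBimodality = 0.75) {
  list(blurSigma = blurSigma, closeRadius = closeRadius,
       minBranchLen = minBranchLen, confScale = confScale,
       coverageFloor = coverageFloor, keepFloor = keepFloor,
       minForeground = minForeground,
       maxForegroundFrac = maxForegroundFrac,
       minBimodality = minBimodality)
}

#' Classical reference pose estimator
#'
#' Binarizes the crop (Otsu after smoothing, plus a closing that bridges
#' the dim vertex corner), keeps the largest 8-connected component and
#' thins it to a skeleton. The skeleton's longest geodesic path — which for
#' a two-arm particle runs tip, vertex, tip, ignoring short spurs — is
#' split at the point minimizing the residual of two total-least-squares
#' line fits; the vertex is refined as the intersection of the two arm
#' lines (pixels near the junction and near the crop border, where thinning
#' distorts the centreline, are excluded from the fits) and the tips are
#' the path endpoints projected onto them. Keypoint confidences decrease
#' monotonically with the line-fit residuals and with the fraction of the
#' particle left unexplained by the two-arm model (see [poseParams()]). On
#' failure (blank crop, no bend in the skeleton, too little foreground) an
#' all-missing pose with confidence 0 is returned — never an error.
#'
#' Tip labels: `tipA` is the tip with the smaller y (then smaller x), a
#' deterministic convention mirroring top-to-bottom annotation habits.
#' For the `hinge-nucleosome` schema the nucleosome is located as the
#' brightest compact secondary component near the arms; if none is found the
#' point is reported missing.
#'
#' @param img crop image (numeric matrix, e.g. from [cropParticles()]).
#' @param schema a [DeviceSchema-class]; the classical backend supports
#'   `hinge` and `hinge-nucleosome`.
#' @param params see [poseParams()].
#' @param particleId identifier for the returned pose.
#' @return a [KeypointPose-class] in crop coordinates.
#' @export
classicalPose <- function(img, schema = hingeSchema(), params = poseParams(),
                          particleId = "p1") {
  if (!schema@name %in% c("hinge", "hinge-nucleosome"))
    stop("the classical backend supports the hinge and hinge-nucleosome ",
         "schemas; got '", schema@name, "'")
  missingPose <- keypointPose(particleId, schema,
                              data.frame(point = schema@keypointNames,
                                         x = NA_real_, y = NA_real_,
                                         confidence = 0))
  norm <- .normalizeImage(img)
  if (is.null(norm)) return(missingPose)
  if (params$blurSigma > 0)
    norm <- EBImage::imageData(EBImage::gblur(EBImage::Image(norm),
                                              sigma = params$blurSigma))
  bin <- norm > .otsu(norm)
  if (sum(bin) < params$minForeground ||
      mean(bin) > params$maxForegroundFrac) return(missingPose)
  w1 <- mean(bin)
  sigmaB <- w1 * (1 - w1) * (mean(norm[bin]) - mean(norm[!bin]))^2
  if (sigmaB / var(as.numeric(norm)) < params$minBimodality)
    return(missingPose)
  if (params$closeRadius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(params$closeRadius) + 1L,
                                "disc")
    bin <- EBImage::imageData(EBImage::closing(EBImage::Image(bin * 1),
                                               brush)) > 0.5
  }
  labels <- .label8(bin)
  sizes <- tabulate(labels[labels > 0], max(labels))
  main <- which.max(sizes)
  mask <- labels == main
  if (sum(mask) < params$minForeground) return(missingPose)
  ana <- .analyzeTwoArm(mask, minBranchLen = params$minBranchLen,
                        excludeRadius = NULL, borderMargin = NULL)
  if (!isTRUE(ana$ok)) return(missingPose)
  tips <- ana$tips
  # deterministic tip labelling: smaller y (then smaller x) is tipA
  o <- order(c(tips[[1]][2], tips[[2]][2]), c(tips[[1]][1], tips[[2]][1]))
  tipA <- tips[[o[1]]]; tipB <- tips[[o[2]]]
  # coverage of the significant foreground (components at least 20% of the
  # main one) by the fitted two-segment model
  strokeW <- sum(mask) / max(ana$skelLength, 1)
  sig <- matrix(FALSE, nrow(bin), ncol(bin))
  for (k in which(sizes >= 0.2 * sizes[main])) sig <- sig | (labels == k)
  coverage <- .segmentCoverage(sig, list(list(ana$vertex, tips[[1]]),
                                         list(ana$vertex, tips[[2]])),
                               max(0.75 * strokeW, 4))
  covScore <- min(1, (coverage / params$coverageFloor)^4)
  kfScore <- pmin(1, ana$keepFrac / params$keepFloor)
  conf <- exp(-(ana$rms / params$confScale)^2) * kfScore * covScore
  confA <- conf[o[1]]; confB <- conf[o[2]]
  confV <- min(confA, confB)
  pts <- data.frame(point = c("tipA", "vertex", "tipB"),
                    x = c(tipA[1], ana$vertex[1], tipB[1]),
                    y = c(tipA[2], ana$vertex[2], tipB[2]),
                    confidence = c(confA, confV, confB))
  if (schema@name == "hinge-nucleosome") {
    nuc <- .locateNucleosome(norm, labels, main, ana)
    pts <- rbind(pts, data.frame(point = "nucleosome", x = nuc$x, y = nuc$y,
                                 confidence = nuc$confidence))
  }
  keypointPose(particleId, schema, pts)
}

# Brightest compact secondary component close to the arm segments.
.locateNucleosome <- function(norm, labels, mainLabel, ana) {
  none <- list(x = NA_real_, y = NA_real_, confidence = 0)
  nLab <- max(labels)
  segs <- list(list(ana$vertex, ana$tips[[1]]), list(ana$vertex, ana$tips[[2]]))
  best <- none; bestBright <- -Inf
  for (k in seq_len(nLab)) {
    if (k == mainLabel) next
    m <- labels == k
    area <- sum(m)
    if (area < 20 || area > 1000) next
    co <- .maskCoords(m)
    cx <- mean(co$x); cy <- mean(co$y)
    # compactness: a blob's area is close to the disc of its radius
    rad <- sqrt(max((co$x - cx)^2 + (co$y - cy)^2))
    if (area < 0.5 * pi * rad^2) next
    d <- min(vapply(segs, function(s) .segDist(cx, cy, s[[1]], s[[2]]),
                    numeric(1)))
    if (d > 6 * rad) next
    bright <- mean(norm[cbind(co$row, co$col)])
    if (bright > bestBright) {
      bestBright <- bright
      best <- list(x = cx, y = cy, confidence = min(1, area / 100))
    }
  }
  best
}

#' Gate poses by keypoint confidence
#'
#' A pose passes only if ALL of its angle-defining keypoints have confidence
#' at or above `threshold` (an angle computed from one untrustworthy point
#' is untrustworthy). Set `points = "all"` to additionally require
#' position-only points to pass.
#'
#' @param poses list of [KeypointPose-class].
#' @param threshold confidence cutoff (default 0.92).
#' @param points `"angle"` (default) or `"all"`.
#' @return the passing poses; the number dropped is reported via `message()`.
#' @export
filterPoseConfidence <- function(poses, threshold = 0.92,
                                 points = c("angle", "all")) {
  stopifnot(threshold >= 0, threshold <= 1)
  points <- match.arg(points)
  if (!length(poses)) return(poses)
  keep <- vapply(poses, function(p) {
    nm <- if (points == "all") p@schema@keypointNames else
      unique(unlist(p@schema@angleDefs))
    all(vapply(nm, function(q) poseConfidence(p, q), numeric(1)) >= threshold)
  }, logical(1))
  if (any(!keep))
    message(sum(!keep), " of ", length(poses),
            " poses dropped below confidence ", threshold)
  poses[keep]
}

#' Resolve the tip-label ambiguity against a reference pose
#'
#' A hinge has no feature distinguishing its two arms, so predicted tip
#' labels may be swapped relative to the reference. Both assignments of
#' predicted tips to reference tips are evaluated and the one minimizing
#' the total tip Euclidean distance is returned; ties keep the original
#' labels. The vertex (and any other points) are untouched, and the hinge
#' angle is invariant under the swap.
#'
#' @param pred,ref complete [KeypointPose-class] objects on a two-tip schema.
#' @param tipNames the two tip names (default `c("tipA", "tipB")`).
#' @return list with `pose` (the canonicalized prediction) and `flipped`
#'   (TRUE iff the swap was chosen).
#' @export
canonicalizeTipLabels <- function(pred, ref, tipNames = c("tipA", "tipB")) {
  for (nm in tipNames) {
    pp <- posePoint(pred, nm); rp <- posePoint(ref, nm)
    if (any(!is.finite(c(pp, rp))))
      stop("canonicalizeTipLabels requires both tips in both poses")
  }
  pA <- posePoint(pred, tipNames[1]); pB <- posePoint(pred, tipNames[2])
  rA <- posePoint(ref, tipNames[1]); rB <- posePoint(ref, tipNames[2])
  dKeep <- sqrt(sum((pA - rA)^2)) + sqrt(sum((pB - rB)^2))
  dSwap <- sqrt(sum((pA - rB)^2)) + sqrt(sum((pB - rA)^2))
  flipped <- dSwap < dKeep
  if (flipped) {
    pts <- pred@points
    iA <- match(tipNames[1], pts$point); iB <- match(tipNames[2], pts$point)
    pts[c(iA, iB), c("x", "y", "confidence")] <-
      pts[c(iB, iA), c("x", "y", "confidence")]
    pred <- keypointPose(pred@particleId, pred@schema, pts)
  }
  list(pose = pred, flipped = flipped)
}

#' Map a pose from crop coordinates back to micrograph coordinates
#'
#' Applies the inverse of the crop affine recorded by [cropParticles()].
#' For unclipped (square-region) crops the map is a similarity transform,
#' so angles are preserved exactly.
#'
#' @param pose a [KeypointPose-class] in crop coordinates.
#' @param provenance the crop's provenance list.
#' @return the pose in micrograph coordinates.
#' @export
mapPoseToMicrograph <- function(pose, provenance) {
  if (is.null(provenance$x0) || is.null(provenance$scaleX))
    stop("missing crop provenance")
  pts <- pose@points
  pts$x <- provenance$x0 + pts$x / provenance$scaleX
  pts$y <- provenance$y0 + pts$y / provenance$scaleY
  keypointPose(pose@particleId, pose@schema, pts)
}
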