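#' Match predicted boxes to ground truth by IoU
#'
#' Greedy one-to-one matching, standard in object-detection evaluation:
#' predictions are visited in order of descending confidence (ties broken by
#' smaller `cx`, then `cy`); each claims the unmatched ground-truth box with
#' the highest IoU if that IoU reaches `iouThreshold` (a true positive),
#' otherwise it counts as a false positive. Unmatched ground-truth boxes are
#' false negatives.
#'
#' @param pred predicted box data.frame (with confidences).
#' @param gt ground-truth box data.frame.
#' @param iouThreshold matching threshold (default 0.3).
#' @return list with `tp`, `fp`, `fn` and `matches`, a data.frame
#'   `predIndex, gtIndex, iou` (indices into the original inputs).
#' @export
matchDetections <- function(pred, gt, iouThreshold = 0.3) {
  assertBoxes(pred)
  if (nrow(gt)) assertBoxes(gt)
  matches <- data.frame(predIndex = integer(), gtIndex = integer(),
                        iou = numeric())
  if (!nrow(pred))
    return(list(tp = 0L, fp = 0L, fn = nrow(gt), matches = matches))
  if (!nrow(gt))
    return(list(tp = 0L, fp = nrow(pred), fn = 0L, matches = matches))
  ord <- order(-pred$confidence, pred$cx, pred$cy)
  M <- iouMatrix(pred, gt)
  freeGt <- rep(TRUE, nrow(gt))
  for (i in ord) {
    cand <- which(freeGt)
    if (!length(cand)) break
    j <- cand[which.max(M[i, cand])]
    if (M[i, j] >= iouThreshold) {
      freeGt[j] <- FALSE
      matches <- rbind(matches, data.frame(predIndex = i, gtIndex = j,
                                           iou = M[i, j]))
    }
  }
  tp <- nrow(matches)
  list(tp = tp, fp = nrow(pred) - tp, fn = sum(freeGt), matches = matches)
}

#' Precision, recall and F1 from confusion counts
#'
#' `Pr = TP / (TP + FP)`, `Re = TP / (TP + FN)`,
#' `F1 = 2 Pr Re / (Pr + Re)`. A metric with a zero denominator is
#' undefined and reported as `NA`; when `Pr + Re = 0` (no true positives
#' against nonzero counts) F1 is reported as 0 with `degenerate = TRUE`.
#' Values are unrounded; round to 2 decimals for presentation.
#'
#' @param tp,fp,fn non-negative confusion counts, not all zero.
#' @return a `DetectionMetrics` list: `tp, fp, fn, precision, recall, f1,
#'   degenerate`.
#' @export
precisionRecallF1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tp + fp + fn > 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  degenerate <- FALSE
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
  else if (precision + recall == 0) { degenerate <- TRUE; 0 }
  else 2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, degenerate = degenerate),
            class = "DetectionMetrics")
}

#' @export
print.DetectionMetrics <- function(x, ...) {
  cat(sprintf(
    "DetectionMetrics: TP %d, FP %d, FN %d | Pr %.2f, Re %.2f, F1 %.2f%s\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f1,
    if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# pair two pose lists by particle id; both poses must be complete
.pairPoses <- function(predPoses, gtPoses) {
  pid <- vapply(predPoses, function(p) p@particleId, character(1))
  gid <- vapply(gtPoses, function(p) p@particleId, character(1))
  common <- intersect(pid, gid)
  pairs <- list()
  for (id in common) {
    p <- predPoses[[match(id, pid)]]
    g <- gtPoses[[match(id, gid)]]
    if (poseComplete(p) && poseComplete(g))
      pairs[[length(pairs) + 1L]] <- list(pred = p, gt = g)
  }
  pairs
}

#' Mean absolute angle error between paired poses
#'
#' Poses are paired by `particleId`; for each pair the absolute difference
#' of the schema angles is taken and averaged over pairs (and over the
#' schema's angles, for multi-angle devices). Tip labelling is irrelevant:
#' the included angle is invariant under tip swaps.
#'
#' @param predPoses,gtPoses lists of complete [KeypointPose-class].
#' @return mean absolute angle error in degrees.
#' @export
meanAngleError <- function(predPoses, gtPoses) {
  pairs <- .pairPoses(predPoses, gtPoses)
  if (!length(pairs)) stop("no complete pose pairs to compare")
  errs <- vapply(pairs, function(pr)
    mean(abs(poseAngles(pr$pred) - poseAngles(pr$gt))), numeric(1))
  mean(errs)
}

#' Per-keypoint spatial errors, 2D standard deviations and flip rate
#'
#' Pairs poses by `particleId`, canonicalizes tip labels against the ground
#' truth ([canonicalizeTipLabels()]), and for every keypoint collects the
#' error vectors `pred - gt` converted to nanometres. The two-dimensional
#' standard deviation of a point is `sqrt(var(dx) + var(dy))` (population
#' variances); the mean radial error is also reported as an alternative
#' summary. `flipRate` is the fraction of pairs where canonicalization
#' chose the tip swap.
#'
#' @param predPoses,gtPoses lists of complete [KeypointPose-class].
#' @param nmPerPx spatial calibration in nm per pixel.
#' @return a `PoseMetrics` list: `errors` (data.frame
#'   `particle_id, point, dx_nm, dy_nm`), `twoDimStd` and `meanRadialError`
#'   (named per point), `flipRate`, `n`.
#' @export
spatialErrors <- function(predPoses, gtPoses, nmPerPx) {
  if (missing(nmPerPx) || !is.finite(nmPerPx) || nmPerPx <= 0)
    stop("a positive nmPerPx calibration is required")
  pairs <- .pairPoses(predPoses, gtPoses)
  if (!length(pairs)) stop("no complete pose pairs to compare")
  rows <- list(); flips <- logical(length(pairs))
  for (i in seq_along(pairs)) {
    pred <- pairs[[i]]$pred; gt <- pairs[[i]]$gt
    if (all(c("tipA", "tipB") %in% pred@schema@keypointNames)) {
      cn <- canonicalizeTipLabels(pred, gt)
      pred <- cn$pose; flips[i] <- cn$flipped
    }
    for (nm in pred@schema@keypointNames) {
      pp <- posePoint(pred, nm); gp <- posePoint(gt, nm)
      rows[[length(rows) + 1L]] <- data.frame(
        particle_id = pred@particleId, point = nm,
        dx_nm = (pp[1] - gp[1]) * nmPerPx, dy_nm = (pp[2] - gp[2]) * nmPerPx)
    }
  }
  errors <- do.call(rbind, rows)
  rownames(errors) <- NULL
  pvar <- function(v) mean((v - mean(v))^2)
  pts <- unique(errors$point)
  twoD <- vapply(pts, function(nm) {
    e <- errors[errors$point == nm, ]
    sqrt(pvar(e$dx_nm) + pvar(e$dy_nm))
  }, numeric(1))
  radial <- vapply(pts, function(nm) {
    e <- errors[errors$point == nm, ]
    mean(sqrt(e$dx_nm^2 + e$dy_nm^2))
  }, numeric(1))
  structure(list(errors = errors, twoDimStd = setNames(twoD, pts),
                 meanRadialError = setNames(radial, pts),
                 flipRate = mean(flips), n = length(pairs)),
            class = "PoseMetrics")
}

#' @export
print.PoseMetrics <- function(x, ...) {
  cat(sprintf("PoseMetrics over %d pose pairs, flip rate %.3f\n", x$n,
              x$flipRate))
  for (nm in names(x$twoDimStd))
    cat(sprintf("  %-12s 2D std %.2f nm, mean radial %.2f nm\n", nm,
                x$twoDimStd[[nm]], x$meanRadialError[[nm]]))
  invisible(x)
}
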