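#' Included angle at a vertex
#'
#' Angle between the vectors vertex->tip1 and vertex->tip2, in degrees in
#' \[0, 180\]. This is the hinge angle when the three points are the two arm
#' tips and the vertex. Invariant under swapping the tips and under any
#' rigid rotation/translation/uniform scaling applied to all three points.
#'
#' @param tip1,vertex,tip2 numeric `c(x, y)` points (pixels, y down).
#' @return angle in degrees in \[0, 180\].
#' @examples
#' angleAtVertex(c(0, 1), c(0, 0), c(1, 0)) # 90
#' @export
angleAtVertex <- function(tip1, vertex, tip2) {
  v1 <- as.numeric(tip1[1:2]) - as.numeric(vertex[1:2])
  v2 <- as.numeric(tip2[1:2]) - as.numeric(vertex[1:2])
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("degenerate input: a tip coincides with the vertex, angle undefined")
  # atan2 of cross/dot is numerically stable near 0 and 180 degrees
  cr <- v1[1] * v2[2] - v1[2] * v2[1]
  dt <- sum(v1 * v2)
  abs(atan2(cr, dt)) * 180 / pi
}

#' Intersection over union of two boxes
#'
#' Boxes are treated as axis-aligned real rectangles (corner = centre +-
#' half extent); no pixel quantization.
#'
#' @param a,b single-row box data.frames or numeric vectors
#'   `c(cx, cy, w, h)`.
#' @return IoU in \[0, 1\].
#' @export
iouBox <- function(a, b) {
  a <- .boxVec(a); b <- .boxVec(b)
  ix <- min(a[1] + a[3] / 2, b[1] + b[3] / 2) -
        max(a[1] - a[3] / 2, b[1] - b[3] / 2)
  iy <- min(a[2] + a[4] / 2, b[2] + b[4] / 2) -
        max(a[2] - a[4] / 2, b[2] - b[4] / 2)
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

.boxVec <- function(b) {
  if (is.data.frame(b)) as.numeric(c(b$cx[1], b$cy[1], b$w[1], b$h[1]))
  else as.numeric(b[1:4])
}

#' Pairwise IoU matrix between two box sets
#'
#' @param a,b box data.frames (see [boundingBoxes()]).
#' @return `nrow(a)` x `nrow(b)` matrix of IoU values.
#' @export
iouMatrix <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  if (!nrow(a) || !nrow(b)) return(out)
  ax0 <- a$cx - a$w / 2; ax1 <- a$cx + a$w / 2
  ay0 <- a$cy - a$h / 2; ay1 <- a$cy + a$h / 2
  bx0 <- b$cx - b$w / 2; bx1 <- b$cx + b$w / 2
  by0 <- b$cy - b$h / 2; by1 <- b$cy + b$h / 2
  for (j in seq_len(nrow(b))) {
    ix <- pmin(ax1, bx1[j]) - pmax(ax0, bx0[j])
    iy <- pmin(ay1, by1[j]) - pmax(ay0, by0[j])
    inter <- pmax(ix, 0) * pmax(iy, 0)
    out[, j] <- inter / (a$w * a$h + b$w[j] * b$h[j] - inter)
  }
  out
}

#' Convert pixels to nanometres
#'
#' @param value length(s) in pixels.
#' @param nmPerPx calibration in nm per pixel (> 0).
#' @return lengths in nanometres.
#' @export
pxToNm <- function(value, nmPerPx) {
  if (!is.finite(nmPerPx) || nmPerPx <= 0)
    stop("nmPerPx must be a positive number")
  value * nmPerPx
}

#' Bounding-box container
#'
#' Boxes are kept as a plain data.frame with columns `cx, cy, w, h,
#' confidence, class_id` (pixels; centre + size; confidence in \[0, 1\];
#' single class 0 for the hinge). This constructor validates the invariants.
#'
#' @param cx,cy box centres in pixels.
#' @param w,h positive box extents in pixels.
#' @param confidence detection confidence in \[0, 1\].
#' @param class_id integer class (default 0).
#' @return data.frame of boxes.
#' @export
boundingBoxes <- function(cx = numeric(), cy = numeric(), w = numeric(),
                          h = numeric(), confidence = numeric(),
                          class_id = 0L) {
  if (!length(confidence)) confidence <- rep(1, length(cx))
  df <- data.frame(cx = cx, cy = cy, w = w, h = h,
                   confidence = confidence,
                   class_id = rep_len(as.integer(class_id), length(cx)))
  assertBoxes(df)
  df
}

#' @describeIn boundingBoxes validate a box data.frame (invisibly TRUE).
#' @param boxes data.frame of boxes.
#' @export
assertBoxes <- function(boxes) {
  need <- c("cx", "cy", "w", "h", "confidence")
  if (!all(need %in% names(boxes)))
    stop("boxes need columns ", paste(need, collapse = ", "))
  if (nrow(boxes)) {
    if (any(boxes$w <= 0 | boxes$h <= 0)) stop("box extents must be positive")
    if (any(boxes$confidence < 0 | boxes$confidence > 1))
      stop("confidences must lie in [0,1]")
  }
  invisible(TRUE)
}

#' @describeIn boundingBoxes aspect ratio max(w,h)/min(w,h) per box (>= 1).
#' @export
boxAspect <- function(boxes) {
  if (!nrow(boxes)) return(numeric())
  pmax(boxes$w, boxes$h) / pmin(boxes$w, boxes$h)
}

#' Angles defined by a pose under its schema
#'
#' Evaluates every angle triple declared in the pose's [DeviceSchema-class]
#' with [angleAtVertex()].
#'
#' @param pose a [KeypointPose-class] with all angle-defining points present.
#' @return named numeric vector, one angle in degrees per schema angle.
#' @export
poseAngles <- function(pose) {
  defs <- pose@schema@angleDefs
  out <- vapply(defs, function(ad) {
    angleAtVertex(posePoint(pose, ad[1]), posePoint(pose, ad[2]),
                  posePoint(pose, ad[3]))
  }, numeric(1))
  names(out) <- vapply(defs, function(ad) paste(ad, collapse = "-"),
                       character(1))
  out
}
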