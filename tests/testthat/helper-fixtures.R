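# Shared fixtures and independent oracles for the test suite.

# Pixel-counting IoU oracle for integer-aligned boxes: rasterize both boxes
# on a unit grid (cell centres, half-open [lo, hi) membership) and count.
iouRaster <- function(a, b) {
  inBox <- function(x, y, bx) {
    x >= bx[1] - bx[3] / 2 & x < bx[1] + bx[3] / 2 &
      y >= bx[2] - bx[4] / 2 & y < bx[2] + bx[4] / 2
  }
  x0 <- floor(min(a[1] - a[3] / 2, b[1] - b[3] / 2))
  x1 <- ceiling(max(a[1] + a[3] / 2, b[1] + b[3] / 2))
  y0 <- floor(min(a[2] - a[4] / 2, b[2] - b[4] / 2))
  y1 <- ceiling(max(a[2] + a[4] / 2, b[2] + b[4] / 2))
  g <- expand.grid(x = seq(x0 + 0.5, x1 - 0.5), y = seq(y0 + 0.5, y1 - 0.5))
  ia <- inBox(g$x, g$y, a); ib <- inBox(g$x, g$y, b)
  sum(ia & ib) / sum(ia | ib)
}

# Brute-force two-sample KS statistic: scan both ECDFs at every sample point.
ksBruteD <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(pts) - stats::ecdf(b)(pts)))
}

# Apply a rigid rotation + translation to a (x, y) point.
rigid <- function(p, theta, shift) {
  c(cos(theta) * p[1] - sin(theta) * p[2] + shift[1],
    sin(theta) * p[1] + cos(theta) * p[2] + shift[2])
}

# Render a single hinge with known angle centred on a small canvas, add
# Gaussian noise, and crop it the way the pipeline would. Returns the crop,
# its provenance and the ground-truth pose mapped into crop coordinates.
makeHingeCrop <- function(angle, rotation = 30, seed = 1, noiseSd = 0.04,
                          canvasSize = 220, cropSize = 200) {
  cfg <- simulationConfig(noiseSd = noiseSd, seed = seed)
  canvas <- matrix(cfg@backgroundLevel, canvasSize, canvasSize)
  rh <- renderHinge(canvas, angle, rotation,
                    center = c(canvasSize / 2, canvasSize / 2), cfg)
  pixels <- rh$pixels
  if (noiseSd > 0) {
    set.seed(seed)
    pixels <- pixels + matrix(rnorm(canvasSize^2, 0, noiseSd),
                              canvasSize, canvasSize)
  }
  m <- Micrograph(pmin(pmax(pixels, 0), 1), cfg@nmPerPx)
  b <- rh$record$box
  side <- max(b["w"], b["h"]) + 8
  box <- boundingBoxes(cx = b["cx"], cy = b["cy"], w = side, h = side)
  crop <- cropParticles(m, box, cropSize)[[1]]
  gtCrop <- poseToCropFrame(rh$record$pose, crop$provenance)
  list(crop = crop$image, provenance = crop$provenance,
       gtPose = rh$record$pose, gtPoseCrop = gtCrop,
       angle = rh$record$angle, micrograph = m, box = box)
}

poseToCropFrame <- function(pose, prov) {
  pts <- pose@points
  pts$x <- (pts$x - prov$x0) * prov$scaleX
  pts$y <- (pts$y - prov$y0) * prov$scaleY
  keypointPose(pose@particleId, pose@schema, pts)
}

# A reduced-size scene for fast end-to-end tests.
smallSimConfig <- function(seed = 1, ...) {
  simulationConfig(imageSize = 480, nTargetHinges = 6,
                   nVerticalDistractors = 1, nAggregates = 1, nFreeBlobs = 2,
                   seed = seed, ...)
}

# Build a complete hinge pose from tip/vertex coordinates.
hingePoseFrom <- function(id, tipA, vertex, tipB, conf = 1) {
  keypointPose(id, hingeSchema(), data.frame(
    point = c("tipA", "vertex", "tipB"),
    x = c(tipA[1], vertex[1], tipB[1]),
    y = c(tipA[2], vertex[2], tipB[2]),
    confidence = rep_len(conf, 3)))
}
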