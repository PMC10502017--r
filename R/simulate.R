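#' SimulationConfig: parameters of the synthetic micrograph generator
#'
#' The generator emulates the feature classes seen in negative-stain TEM
#' micrographs of two-arm origami hinges: isolated target hinges with a known
#' angle distribution, single-rod distractors (a hinge deposited edge-on
#' shows only one arm), local aggregates of overlapping hinges, compact
#' blobs, and a background of base level + low-frequency stain mottle +
#' Gaussian noise. Particles are bright on a dark background (the
#' negative-stain convention: structures appear light against stain); set
#' `invert = TRUE` for the opposite polarity.
#'
#' @slot imageSize image side in pixels (default 960, the working scale).
#' @slot nmPerPx nm per pixel (default 1.4: a 70 nm arm is 50 px).
#' @slot armLengthNm,armWidthNm hinge arm length/width in nm (70 / 10).
#' @slot angleLaw list describing the hinge-angle law: `family` one of
#'   `"uniform"`, `"gaussian"`, `"truncated-gaussian"`,
#'   `"empirical-histogram"`, plus its parameters (`mean`, `sd`, `min`,
#'   `max`, or `edges` + `probs`). Support must lie in \[0, 180\] degrees.
#' @slot nTargetHinges,nVerticalDistractors,nAggregates,nFreeBlobs,nBorderHinges
#'   particle counts per image. Border hinges are deliberately clipped by the
#'   image edge (boundary clutter); they are not target ground truth.
#' @slot particleIntensity brightness added by a particle (default 0.35).
#' @slot backgroundLevel base background intensity (0.25).
#' @slot noiseSd per-pixel Gaussian noise sd (0.04).
#' @slot mottleScale correlation length of the stain mottle in px (96).
#' @slot mottleSd amplitude of the mottle (0.03).
#' @slot edgeSigma Gaussian blur of particle edges in px (1.0).
#' @slot invert render dark particles on bright background.
#' @slot seed RNG seed; a fixed seed gives byte-identical output.
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(imageSize = "numeric", nmPerPx = "numeric",
                 armLengthNm = "numeric", armWidthNm = "numeric",
                 angleLaw = "list", nTargetHinges = "numeric",
                 nVerticalDistractors = "numeric", nAggregates = "numeric",
                 nFreeBlobs = "numeric", nBorderHinges = "numeric",
                 particleIntensity = "numeric", backgroundLevel = "numeric",
                 noiseSd = "numeric", mottleScale = "numeric",
                 mottleSd = "numeric", edgeSigma = "numeric",
                 invert = "logical", seed = "numeric"),
  validity = function(object) {
    cnt <- c(object@nTargetHinges, object@nVerticalDistractors,
             object@nAggregates, object@nFreeBlobs, object@nBorderHinges)
    if (any(cnt < 0)) return("particle counts must be >= 0")
    if (object@imageSize <= 0) return("imageSize must be positive")
    if (object@nmPerPx <= 0) return("nmPerPx must be positive")
    if (object@noiseSd < 0 || object@mottleSd < 0)
      return("noise levels must be >= 0")
    law <- object@angleLaw
    if (is.null(law$family)) return("angleLaw needs a 'family'")
    TRUE
  })

#' Construct a SimulationConfig
#'
#' @param imageSize,nmPerPx,armLengthNm,armWidthNm,angleLaw see
#'   [SimulationConfig-class].
#' @param nTargetHinges,nVerticalDistractors,nAggregates,nFreeBlobs,nBorderHinges
#'   per-image particle counts.
#' @param particleIntensity,backgroundLevel,noiseSd,mottleScale,mottleSd,edgeSigma
#'   appearance parameters.
#' @param invert dark-on-bright polarity.
#' @param seed RNG seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(imageSize = 960, nmPerPx = 1.4,
                             armLengthNm = 70, armWidthNm = 10,
                             angleLaw = list(family = "truncated-gaussian",
                                             mean = 90, sd = 15,
                                             min = 0, max = 180),
                             nTargetHinges = 20, nVerticalDistractors = 3,
                             nAggregates = 2, nFreeBlobs = 4,
                             nBorderHinges = 0,
                             particleIntensity = 0.35,
                             backgroundLevel = 0.25, noiseSd = 0.04,
                             mottleScale = 96, mottleSd = 0.03,
                             edgeSigma = 1.0, invert = FALSE, seed = 1) {
  new("SimulationConfig", imageSize = imageSize, nmPerPx = nmPerPx,
      armLengthNm = armLengthNm, armWidthNm = armWidthNm,
      angleLaw = angleLaw, nTargetHinges = nTargetHinges,
      nVerticalDistractors = nVerticalDistractors, nAggregates = nAggregates,
      nFreeBlobs = nFreeBlobs, nBorderHinges = nBorderHinges,
      particleIntensity = particleIntensity,
      backgroundLevel = backgroundLevel, noiseSd = noiseSd,
      mottleScale = mottleScale, mottleSd = mottleSd, edgeSigma = edgeSigma,
      invert = invert, seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d px, %.3g nm/px, arms %.3g x %.3g nm, %s angles,\n",
    as.integer(object@imageSize), object@nmPerPx, object@armLengthNm,
    object@armWidthNm, object@angleLaw$family))
  cat(sprintf(
    "  %d hinges + %d rods + %d aggregates + %d blobs + %d border, seed %d\n",
    as.integer(object@nTargetHinges),
    as.integer(object@nVerticalDistractors), as.integer(object@nAggregates),
    as.integer(object@nFreeBlobs), as.integer(object@nBorderHinges),
    as.integer(object@seed)))
})

#' Sample hinge angles from a distribution law
#'
#' @param angleLaw a law list (see [SimulationConfig-class]).
#' @param n number of draws.
#' @param seed optional seed; the caller's RNG state is preserved.
#' @return `n` angles in degrees, all in \[0, 180\].
#' @export
sampleAngles <- function(angleLaw, n, seed = NULL) {
  stopifnot(n >= 0)
  .withSeed(seed, .sampleAnglesImpl(angleLaw, n))
}

.sampleAnglesImpl <- function(law, n) {
  if (n == 0) return(numeric())
  fam <- law$family
  if (is.null(fam)) stop("angleLaw needs a 'family'")
  lo <- if (!is.null(law$min)) law$min else 0
  hi <- if (!is.null(law$max)) law$max else 180
  if (lo < 0 || hi > 180 || lo >= hi)
    stop("angle law support must lie within [0, 180]")
  if (fam == "uniform") return(runif(n, lo, hi))
  if (fam %in% c("gaussian", "truncated-gaussian")) {
    if (is.null(law$mean) || is.null(law$sd) || law$sd < 0)
      stop("gaussian law needs mean and sd >= 0")
    if (law$sd == 0) return(rep(law$mean, n))
    out <- numeric(0)
    for (it in 1:1000) {   # rejection sampling onto the support
      draw <- rnorm(n - length(out), law$mean, law$sd)
      out <- c(out, draw[draw >= lo & draw <= hi])
      if (length(out) >= n) return(out[seq_len(n)])
    }
    stop("angle law support has negligible mass in [", lo, ", ", hi, "]")
  }
  if (fam == "empirical-histogram") {
    e <- law$edges; p <- law$probs
    if (is.null(e) || is.null(p) || length(p) != length(e) - 1L)
      stop("empirical-histogram law needs edges and probs")
    if (any(e < 0 | e > 180) || any(diff(e) <= 0) || any(p < 0) || sum(p) <= 0)
      stop("invalid empirical-histogram parameters")
    bin <- sample.int(length(p), n, replace = TRUE, prob = p)
    return(runif(n, e[bin], e[bin + 1L]))
  }
  stop("unknown angle law family '", fam, "'")
}

# Geometry of a rendered hinge. The vertex sits at `center`; the two arms
# leave the vertex along the bisector `rotation` +/- angle/2. Each arm is a
# rectangle whose INNER edge (the edge facing the other arm) runs from the
# vertex to the tip, mirroring the annotation rule of placing keypoints on
# the inner arm lines; the rectangle extends outward by the arm width.
.hingeGeometry <- function(angle, rotation, center, Lpx, Wpx) {
  a1 <- (rotation - angle / 2) * pi / 180
  a2 <- (rotation + angle / 2) * pi / 180
  u1 <- c(cos(a1), sin(a1)); u2 <- c(cos(a2), sin(a2))
  n1 <- c(-u1[2], u1[1]); if (sum(n1 * u2) > 0) n1 <- -n1
  n2 <- c(-u2[2], u2[1]); if (sum(n2 * u1) > 0) n2 <- -n2
  arms <- list(list(u = u1, nrm = n1), list(u = u2, nrm = n2))
  corners <- rbind(center,
                   center + Lpx * u1, center + Lpx * u1 + Wpx * n1,
                   center + Wpx * n1,
                   center + Lpx * u2, center + Lpx * u2 + Wpx * n2,
                   center + Wpx * n2)
  list(arms = arms, corners = corners,
       tips = list(center + Lpx * u1, center + Lpx * u2), vertex = center)
}

# Paint an arm-set mask onto a canvas patch and return the updated canvas.
# Membership is evaluated at pixel centres; edges are softened by a Gaussian
# blur of sd edgeSigma.
.paintArms <- function(pixels, arms, vertex, Lpx, Wpx, intensity, edgeSigma,
                       allowClip = FALSE) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  pad <- ceiling(3 * edgeSigma) + 2
  xs <- unlist(lapply(arms, function(a)
    c(vertex[1], vertex[1] + Lpx * a$u[1] + c(0, Wpx * a$nrm[1]),
      vertex[1] + Wpx * a$nrm[1])))
  ys <- unlist(lapply(arms, function(a)
    c(vertex[2], vertex[2] + Lpx * a$u[2] + c(0, Wpx * a$nrm[2]),
      vertex[2] + Wpx * a$nrm[2])))
  x0 <- floor(min(xs)) - pad; x1 <- ceiling(max(xs)) + pad
  y0 <- floor(min(ys)) - pad; y1 <- ceiling(max(ys)) + pad
  if (!allowClip && (x0 < 0 || y0 < 0 || x1 > nc || y1 > nr))
    stop("particle would exceed the canvas")
  x0 <- max(0, x0); y0 <- max(0, y0); x1 <- min(nc, x1); y1 <- min(nr, y1)
  if (x1 - x0 < 2 || y1 - y0 < 2) return(pixels)
  px <- (x0 + 1):x1; py <- (y0 + 1):y1
  X <- matrix(px - 0.5, nrow = length(py), ncol = length(px), byrow = TRUE)
  Y <- matrix(py - 0.5, nrow = length(py), ncol = length(px))
  mask <- matrix(FALSE, length(py), length(px))
  for (a in arms) {
    t <- (X - vertex[1]) * a$u[1] + (Y - vertex[2]) * a$u[2]
    s <- (X - vertex[1]) * a$nrm[1] + (Y - vertex[2]) * a$nrm[2]
    mask <- mask | (t >= 0 & t <= Lpx & s >= 0 & s <= Wpx)
  }
  soft <- mask
  if (edgeSigma > 0)
    soft <- EBImage::imageData(EBImage::gblur(EBImage::Image(mask * 1),
                                              sigma = edgeSigma))
  pixels[py, px] <- pixels[py, px] + intensity * soft
  pixels
}

#' Render a single hinge onto a canvas with exact ground truth
#'
#' Draws two bright rectangular arms sharing the vertex at `center`, with
#' included angle `angle`, the whole particle rotated by `rotation` (the
#' bisector direction). Keypoint ground truth follows the inner-edge
#' annotation rule: the vertex is the intersection of the two inner arm
#' edges and the tips are the inner-edge endpoints. The ground-truth box is
#' the tight axis-aligned extent of the drawn rectangles (it contains all
#' keypoints by construction).
#'
#' @param canvas numeric matrix to draw on (modified copy returned).
#' @param angle included hinge angle in degrees.
#' @param rotation global particle rotation in degrees.
#' @param center vertex position `c(x, y)` in pixels.
#' @param config a [SimulationConfig-class].
#' @param particleId identifier for the ground-truth record.
#' @return list with `pixels` (updated canvas) and `record` (a list with
#'   `particleId`, `box`, `pose` ([KeypointPose-class]), `angle`, `class`).
#' @export
renderHinge <- function(canvas, angle, rotation, center, config,
                        particleId = "p1") {
  Lpx <- config@armLengthNm / config@nmPerPx
  Wpx <- config@armWidthNm / config@nmPerPx
  g <- .hingeGeometry(angle, rotation, center, Lpx, Wpx)
  pixels <- .paintArms(canvas, g$arms, g$vertex, Lpx, Wpx,
                       config@particleIntensity, config@edgeSigma)
  box <- .cornersToBox(g$corners)
  pose <- keypointPose(particleId, hingeSchema(), data.frame(
    point = c("tipA", "vertex", "tipB"),
    x = c(g$tips[[1]][1], g$vertex[1], g$tips[[2]][1]),
    y = c(g$tips[[1]][2], g$vertex[2], g$tips[[2]][2]),
    confidence = 1))
  list(pixels = pixels,
       record = list(particleId = particleId, box = box, pose = pose,
                     angle = angle, class = "target_hinge"))
}

.cornersToBox <- function(corners, clip = NULL) {
  x0 <- min(corners[, 1]); x1 <- max(corners[, 1])
  y0 <- min(corners[, 2]); y1 <- max(corners[, 2])
  if (!is.null(clip)) {
    x0 <- max(0, x0); y0 <- max(0, y0)
    x1 <- min(clip[1], x1); y1 <- min(clip[2], y1)
  }
  c(cx = (x0 + x1) / 2, cy = (y0 + y1) / 2, w = x1 - x0, h = y1 - y0)
}

#' Generate one synthetic micrograph with complete ground truth
#'
#' Places the configured counts of isolated target hinges, single-rod
#' distractors, aggregates (2-3 overlapping hinges), free blobs and
#' (optionally) border-clipped hinges over the background model, without
#' overlap between distinct particles (rejection sampling, up to 1000 tries
#' per particle). Deterministic under `config@seed`.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `micrograph` ([Micrograph-class]), `truth` (data.frame
#'   `particle_id, class, cx, cy, w, h, angle`) and `poses` (named list of
#'   ground-truth [KeypointPose-class] for target hinges).
#' @export
generateMicrograph <- function(config) {
  validObject(config)
  .withSeed(config@seed, .generateMicrographImpl(config))
}

.generateMicrographImpl <- function(config) {
  size <- as.integer(config@imageSize)
  Lpx <- config@armLengthNm / config@nmPerPx
  Wpx <- config@armWidthNm / config@nmPerPx
  pixels <- matrix(config@backgroundLevel, size, size)
  if (config@mottleSd > 0 && config@mottleScale > 0) {
    k <- max(2L, as.integer(ceiling(size / config@mottleScale)) + 1L)
    coarse <- matrix(rnorm(k * k, 0, config@mottleSd), k, k)
    pixels <- pixels +
      EBImage::imageData(EBImage::resize(EBImage::Image(coarse), w = size,
                                         h = size))
  }
  # rejection-sampled particle centres with disjoint bounding radii
  placed <- matrix(numeric(0), ncol = 3) # x, y, radius
  place <- function(radius, margin, what) {
    for (try in 1:1000) {
      x <- runif(1, margin, size - margin)
      y <- runif(1, margin, size - margin)
      if (!nrow(placed) ||
          all(sqrt((placed[, 1] - x)^2 + (placed[, 2] - y)^2) >
              placed[, 3] + radius + 4)) {
        placed <<- rbind(placed, c(x, y, radius))
        return(c(x, y))
      }
    }
    stop("could not place ", what, " without overlap after 1000 tries (",
         nrow(placed), " particles placed)")
  }
  truth <- list(); poses <- list()
  addTruth <- function(id, cls, box, angle = NA_real_) {
    truth[[length(truth) + 1L]] <<- data.frame(
      particle_id = id, class = cls, cx = box[1], cy = box[2],
      w = box[3], h = box[4], angle = angle)
  }
  # bounding circle of a corner set, centred on the extent (not the vertex)
  boundCircle <- function(corners, pad = 4) {
    ctr <- c(mean(range(corners[, 1])), mean(range(corners[, 2])))
    rad <- sqrt(max((corners[, 1] - ctr[1])^2 + (corners[, 2] - ctr[2])^2))
    list(center = ctr, radius = rad + pad)
  }
  hingeRadius <- Lpx + Wpx + 6
  # place the largest objects first so packing cannot strand them
  for (i in seq_len(as.integer(config@nAggregates))) {
    nSub <- sample(2:3, 1)
    ctr <- place(1.6 * Lpx, 1.6 * Lpx + 2, "aggregate")
    allCorners <- NULL
    for (s in seq_len(nSub)) {
      off <- runif(2, -Lpx / 3, Lpx / 3)
      ang <- .sampleAnglesImpl(config@angleLaw, 1)
      g <- .hingeGeometry(ang, runif(1, 0, 360), ctr + off, Lpx, Wpx)
      pixels <- .paintArms(pixels, g$arms, g$vertex, Lpx, Wpx,
                           config@particleIntensity, config@edgeSigma,
                           allowClip = TRUE)
      allCorners <- rbind(allCorners, g$corners)
    }
    addTruth(sprintf("agg%02d", i), "aggregate",
             .cornersToBox(allCorners, clip = c(size, size)))
  }
  nT <- as.integer(config@nTargetHinges)
  angles <- .sampleAnglesImpl(config@angleLaw, nT)
  for (i in seq_len(nT)) {
    rot <- runif(1, 0, 360)
    g0 <- .hingeGeometry(angles[i], rot, c(0, 0), Lpx, Wpx)
    bc <- boundCircle(g0$corners)
    ctr <- place(bc$radius, bc$radius + 2, "target hinge")
    vertex <- ctr - bc$center
    id <- sprintf("p%03d", i)
    rh <- renderHinge(pixels, angles[i], rot, vertex, config,
                      particleId = id)
    pixels <- rh$pixels
    addTruth(id, "target_hinge", rh$record$box, angles[i])
    poses[[id]] <- rh$record$pose
  }
  for (i in seq_len(as.integer(config@nVerticalDistractors))) {
    a <- runif(1, 0, 360) * pi / 180
    u <- c(cos(a), sin(a)); nrm <- c(-u[2], u[1])
    corners0 <- rbind(c(0, 0), Lpx * u, Lpx * u + Wpx * nrm, Wpx * nrm)
    bc <- boundCircle(corners0)
    ctr <- place(bc$radius, bc$radius + 2, "rod distractor")
    org <- ctr - bc$center
    arms <- list(list(u = u, nrm = nrm))
    pixels <- .paintArms(pixels, arms, org, Lpx, Wpx,
                         config@particleIntensity, config@edgeSigma)
    corners <- sweep(corners0, 2, org, "+")
    addTruth(sprintf("rod%02d", i), "vertical_distractor",
             .cornersToBox(corners))
  }
  for (i in seq_len(as.integer(config@nFreeBlobs))) {
    rad <- runif(1, 3, 6)
    ctr <- place(3 * rad, 3 * rad + 2, "blob")
    px <- max(1, floor(ctr[1] - 3 * rad)):min(size, ceiling(ctr[1] + 3 * rad))
    py <- max(1, floor(ctr[2] - 3 * rad)):min(size, ceiling(ctr[2] + 3 * rad))
    X <- matrix(px - 0.5, length(py), length(px), byrow = TRUE)
    Y <- matrix(py - 0.5, length(py), length(px))
    r2 <- (X - ctr[1])^2 + (Y - ctr[2])^2
    pixels[py, px] <- pixels[py, px] +
      config@particleIntensity * exp(-r2 / (2 * (rad / 1.5)^2))
    addTruth(sprintf("blob%02d", i), "blob",
             c(ctr[1], ctr[2], 4 * rad, 4 * rad))
  }
  # boundary clutter: hinges whose vertex sits close to an edge, so part of
  # the particle is cut off by the image border (never target ground truth)
  for (i in seq_len(as.integer(config@nBorderHinges))) {
    side <- sample(4, 1)
    along <- runif(1, hingeRadius, size - hingeRadius)
    off <- runif(1, 0.1 * Lpx, 0.5 * Lpx)
    ctr <- switch(side, c(along, off), c(along, size - off),
                  c(off, along), c(size - off, along))
    placed <- rbind(placed, c(ctr[1], ctr[2], hingeRadius))
    ang <- .sampleAnglesImpl(config@angleLaw, 1)
    g <- .hingeGeometry(ang, runif(1, 0, 360), ctr, Lpx, Wpx)
    pixels <- .paintArms(pixels, g$arms, g$vertex, Lpx, Wpx,
                         config@particleIntensity, config@edgeSigma,
                         allowClip = TRUE)
    addTruth(sprintf("border%02d", i), "border_hinge",
             .cornersToBox(g$corners, clip = c(size, size)), ang)
  }
  if (config@noiseSd > 0)
    pixels <- pixels + matrix(rnorm(size * size, 0, config@noiseSd),
                              size, size)
  pixels <- pmin(pmax(pixels, 0), 1)
  if (config@invert) pixels <- 1 - pixels
  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(particle_id = character(), class = character(),
               cx = numeric(), cy = numeric(), w = numeric(), h = numeric(),
               angle = numeric())
  rownames(truthDf) <- NULL
  list(micrograph = Micrograph(pixels, config@nmPerPx), truth = truthDf,
       poses = poses)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `nImages` PNG micrographs, YOLO-format ground-truth label files
#' (target hinges only, class 0), a keypoint ground-truth CSV, a truth CSV
#' covering all particle classes, and a JSON manifest listing files,
#' per-image seeds and the angle law. Per-image seeds are derived
#' deterministically from `config@seed`.
#'
#' @param config a [SimulationConfig-class].
#' @param nImages number of images.
#' @param outDir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
generateDataset <- function(config, nImages, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  kpAll <- list(); truthAll <- list()
  for (i in seq_len(nImages)) {
    cfg <- config
    cfg@seed <- deriveSeed(config@seed, paste0("image", i))
    gen <- generateMicrograph(cfg)
    imgName <- sprintf("img_%03d", i)
    writeMicrograph(gen$micrograph, file.path(outDir, paste0(imgName, ".png")))
    tgt <- gen$truth[gen$truth$class == "target_hinge", , drop = FALSE]
    writeYoloLabels(boundingBoxes(cx = tgt$cx, cy = tgt$cy, w = tgt$w,
                                  h = tgt$h),
                    file.path(outDir, paste0(imgName, ".txt")),
                    imageSize = config@imageSize, writeConfidence = FALSE)
    if (length(gen$poses))
      kpAll[[i]] <- .posesToKeypointDf(gen$poses, image = imgName)
    if (nrow(gen$truth)) {
      gt <- gen$truth; gt$image <- imgName
      truthAll[[i]] <- gt
    }
    entries[[i]] <- list(image = paste0(imgName, ".png"),
                         labels = paste0(imgName, ".txt"),
                         seed = cfg@seed, n_targets = nrow(tgt))
  }
  kpDf <- if (length(kpAll)) do.call(rbind, kpAll) else
    .posesToKeypointDf(list(), "")
  write.csv(kpDf, file.path(outDir, "keypoints.csv"), row.names = FALSE)
  if (length(truthAll))
    write.csv(do.call(rbind, truthAll), file.path(outDir, "truth.csv"),
              row.names = FALSE)
  manifest <- list(n_images = nImages, image_size = config@imageSize,
                   nm_per_px = config@nmPerPx, seed = config@seed,
                   angle_law = config@angleLaw, images = entries)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
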