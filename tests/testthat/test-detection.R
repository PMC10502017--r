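test_that("non-maximum suppression keeps the best of overlapping boxes", {
  empty <- boundingBoxes()
  expect_equal(nrow(nms(empty)), 0)
  two <- boundingBoxes(cx = c(5, 5), cy = c(5, 5), w = c(4, 4), h = c(4, 4),
                       confidence = c(0.9, 0.8))
  out <- nms(two, 0.3)
  expect_equal(nrow(out), 1)
  expect_equal(out$confidence, 0.9)
  apart <- boundingBoxes(cx = c(5, 50), cy = c(5, 50), w = c(4, 4),
                         h = c(4, 4), confidence = c(0.9, 0.8))
  expect_equal(nrow(nms(apart, 0.3)), 2)
})

test_that("nms output is a subset with pairwise IoU below the threshold", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 30
    b <- boundingBoxes(cx = runif(n, 0, 100), cy = runif(n, 0, 100),
                       w = runif(n, 5, 25), h = runif(n, 5, 25),
                       confidence = runif(n))
    out <- nms(b, 0.3)
    expect_lte(nrow(out), n)
    # every survivor appears in the input
    key <- function(d) paste(d$cx, d$cy, d$w, d$h, d$confidence)
    expect_true(all(key(out) %in% key(b)))
    if (nrow(out) > 1) {
      M <- iouMatrix(out, out)
      diag(M) <- 0
      expect_lte(max(M), 0.3)
    }
  }
})

test_that("the bounding-box-size filter removes high-aspect boxes and re-squares survivors", {
  b <- boundingBoxes(cx = c(10, 20, 30), cy = c(10, 20, 30),
                     w = c(60, 52, 30), h = c(30, 48, 30),
                     confidence = c(0.9, 0.8, 0.7))
  out <- bbfFilter(b, maxAspect = 1.5, squareSize = 50)
  expect_equal(nrow(out), 2)            # aspect 2.0 removed
  expect_equal(out$cx, c(20, 30))       # centres unchanged, order preserved
  expect_true(all(out$w == 50 & out$h == 50))
  expect_true(all(boxAspect(out) == 1))
  expect_equal(nrow(bbfFilter(boundingBoxes())), 0)
})

test_that("confidence filtering is inclusive at the threshold", {
  b <- boundingBoxes(cx = 1:3, cy = 1:3, w = 2, h = 2,
                     confidence = c(0.9, 0.47, 0.46))
  expect_equal(nrow(filterByConfidence(b, 0.47)), 2)
  expect_equal(nrow(filterByConfidence(b, 0)), 3)
  expect_equal(nrow(filterByConfidence(b, 1)), 0)
})

test_that("the classical detector returns nothing on particle-free images", {
  expect_equal(nrow(classicalDetect(matrix(0.3, 200, 200))), 0)
  set.seed(8)
  noise <- matrix(0.25 + rnorm(200 * 200, 0, 0.04), 200, 200)
  expect_equal(nrow(classicalDetect(noise)), 0)
})

test_that("a clean isolated hinge is detected as one box overlapping ground truth", {
  cfg <- simulationConfig(imageSize = 300, nTargetHinges = 1,
                          nVerticalDistractors = 0, nAggregates = 0,
                          nFreeBlobs = 0, noiseSd = 0, mottleSd = 0,
                          seed = 13)
  g <- generateMicrograph(cfg)
  boxes <- classicalDetect(g$micrograph)
  expect_equal(nrow(boxes), 1)
  tr <- g$truth[1, ]
  expect_gte(iouBox(boxes[1, ], c(tr$cx, tr$cy, tr$w, tr$h)), 0.5)
})

test_that("aggregates score lower confidence than isolated hinges", {
  cfg <- simulationConfig(imageSize = 500, nTargetHinges = 1,
                          nVerticalDistractors = 0, nAggregates = 1,
                          nFreeBlobs = 0, noiseSd = 0, mottleSd = 0,
                          seed = 17)
  g <- generateMicrograph(cfg)
  boxes <- classicalDetect(g$micrograph)
  tr <- g$truth
  hinge <- tr[tr$class == "target_hinge", ]
  agg <- tr[tr$class == "aggregate", ]
  dHinge <- sqrt((boxes$cx - hinge$cx)^2 + (boxes$cy - hinge$cy)^2)
  dAgg <- sqrt((boxes$cx - agg$cx)^2 + (boxes$cy - agg$cy)^2)
  confHinge <- boxes$confidence[which.min(dHinge)]
  confAgg <- if (any(dAgg < dHinge)) max(boxes$confidence[dAgg < dHinge]) else 0
  expect_gt(confHinge, confAgg)
  expect_gte(confHinge, 0.47)
  expect_lt(confAgg, 0.47)
})

test_that("crops record an exact invertible affine and preserve angles", {
  cfg <- smallSimConfig(seed = 6)
  g <- generateMicrograph(cfg)
  tr <- g$truth[g$truth$class == "target_hinge", ][1, ]
  box <- boundingBoxes(cx = tr$cx, cy = tr$cy, w = 50, h = 50)
  crop <- cropParticles(g$micrograph, box, 200)[[1]]
  expect_equal(dim(crop$image), c(200, 200))
  prov <- crop$provenance
  # round trip crop -> micrograph -> crop is the identity
  p <- c(37.25, 121.5)
  back <- c((prov$x0 + p[1] / prov$scaleX - prov$x0) * prov$scaleX,
            (prov$y0 + p[2] / prov$scaleY - prov$y0) * prov$scaleY)
  expect_equal(back, p, tolerance = 1e-9)
  # ground-truth keypoints mapped into the crop give the same angle
  gtPose <- g$poses[[tr$particle_id]]
  gtCrop <- poseToCropFrame(gtPose, prov)
  expect_equal(unname(poseAngles(gtCrop)), unname(poseAngles(gtPose)),
               tolerance = 1e-9)
  # a box hanging over the border is clipped, not an error
  edgeBox <- boundingBoxes(cx = 3, cy = 3, w = 50, h = 50)
  ec <- cropParticles(g$micrograph, edgeBox, 200)[[1]]
  expect_true(ec$provenance$clipped)
  expect_warning(
    cropParticles(g$micrograph, boundingBoxes(cx = -60, cy = -60, w = 20,
                                              h = 20), 200),
    "zero area")
})

test_that("detect + filters achieve high precision and recall on synthetic scenes", {
  tp <- 0; fp <- 0; fn <- 0
  for (i in 1:4) {
    cfg <- simulationConfig(seed = deriveSeed(99, paste0("detprop", i)))
    g <- generateMicrograph(cfg)
    final <- bbfFilter(nms(filterByConfidence(
      classicalDetect(g$micrograph), 0.47), 0.3))
    tgt <- g$truth[g$truth$class == "target_hinge", ]
    gtB <- boundingBoxes(cx = tgt$cx, cy = tgt$cy, w = tgt$w, h = tgt$h)
    mt <- matchDetections(final, gtB, 0.3)
    tp <- tp + mt$tp; fp <- fp + mt$fp; fn <- fn + mt$fn
  }
  m <- precisionRecallF1(tp, fp, fn)
  expect_gte(m$precision, 0.9)
  expect_gte(m$recall, 0.9)
})

test_that("the BBF removes boundary clutter without sacrificing precision", {
  tpPre <- 0; fpPre <- 0; tpPost <- 0; fpPost <- 0
  for (i in 1:2) {
    cfg <- simulationConfig(nBorderHinges = 4,
                            seed = deriveSeed(55, paste0("border", i)))
    g <- generateMicrograph(cfg)
    pre <- nms(filterByConfidence(classicalDetect(g$micrograph), 0.47), 0.3)
    post <- bbfFilter(pre)
    tgt <- g$truth[g$truth$class == "target_hinge", ]
    gtB <- boundingBoxes(cx = tgt$cx, cy = tgt$cy, w = tgt$w, h = tgt$h)
    m1 <- matchDetections(pre, gtB, 0.3)
    m2 <- matchDetections(post, gtB, 0.3)
    tpPre <- tpPre + m1$tp; fpPre <- fpPre + m1$fp
    tpPost <- tpPost + m2$tp; fpPost <- fpPost + m2$fp
  }
  expect_lt(fpPost, fpPre)
  prPre <- tpPre / (tpPre + fpPre)
  prPost <- tpPost / (tpPost + fpPost)
  expect_gte(prPost, prPre)
})
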