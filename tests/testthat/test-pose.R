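test_that("a clean 90-degree hinge crop is measured within 4 degrees", {
  fx <- makeHingeCrop(90, rotation = 25, seed = 2)
  pose <- classicalPose(fx$crop)
  expect_true(poseComplete(pose))
  expect_lt(abs(unname(poseAngles(pose)) - 90), 4)
})

test_that("rotating a crop by 90 degrees leaves the measured angle unchanged", {
  fx <- makeHingeCrop(104, rotation = 10, seed = 3)
  a1 <- unname(poseAngles(classicalPose(fx$crop)))
  rot <- t(fx$crop)[, nrow(fx$crop):1]   # 90-degree image rotation
  a2 <- unname(poseAngles(classicalPose(rot)))
  expect_lt(abs(a1 - a2), 1)
})

test_that("blank crops yield an all-missing pose with zero confidence", {
  flat <- classicalPose(matrix(0.3, 200, 200))
  expect_false(poseComplete(flat))
  expect_true(all(flat@points$confidence == 0))
  set.seed(4)
  noisy <- classicalPose(matrix(0.25 + rnorm(200^2, 0, 0.04), 200, 200))
  expect_false(poseComplete(noisy))
  expect_error(classicalPose(matrix(0.3, 50, 50), steriDynSchema()),
               "schema")
})

test_that("pose confidence gating requires every angle point to pass", {
  mk <- function(confs) keypointPose("p", hingeSchema(), data.frame(
    point = c("tipA", "vertex", "tipB"), x = c(0, 1, 2), y = c(0, 1, 0),
    confidence = confs))
  keep <- mk(c(0.95, 0.93, 0.99))
  drop <- mk(c(0.95, 0.91, 0.99))
  expect_length(filterPoseConfidence(list(keep), 0.92), 1)
  expect_length(suppressMessages(filterPoseConfidence(list(drop), 0.92)), 0)
  expect_length(filterPoseConfidence(list(), 0.92), 0)
  expect_length(suppressMessages(
    filterPoseConfidence(list(keep, drop), 0.92)), 1)
})

test_that("tip-label canonicalization picks the assignment of least distance", {
  ref <- hingePoseFrom("p", c(0, 0), c(5, 5), c(10, 0))
  same <- canonicalizeTipLabels(ref, ref)
  expect_false(same$flipped)
  swapped <- hingePoseFrom("p", c(10, 0), c(5, 5), c(0, 0))
  cn <- canonicalizeTipLabels(swapped, ref)
  expect_true(cn$flipped)
  expect_equal(posePoint(cn$pose, "tipA"), posePoint(ref, "tipA"))
  # the included angle never changes
  expect_equal(unname(poseAngles(cn$pose)), unname(poseAngles(swapped)))
  # symmetric tie keeps the original labels
  tie <- hingePoseFrom("p", c(5, 1), c(5, 5), c(5, 1))
  expect_false(canonicalizeTipLabels(tie, tie)$flipped)
  incomplete <- keypointPose("p", hingeSchema(), data.frame(
    point = "vertex", x = 1, y = 1, confidence = 1))
  expect_error(canonicalizeTipLabels(incomplete, ref), "tips")
})

test_that("poses map back to micrograph coordinates exactly", {
  fx <- makeHingeCrop(95, rotation = 40, seed = 6)
  pose <- classicalPose(fx$crop)
  mapped <- mapPoseToMicrograph(pose, fx$provenance)
  back <- poseToCropFrame(mapped, fx$provenance)
  expect_equal(back@points$x, pose@points$x, tolerance = 1e-9)
  expect_equal(back@points$y, pose@points$y, tolerance = 1e-9)
  expect_equal(unname(poseAngles(mapped)), unname(poseAngles(pose)),
               tolerance = 1e-9)
  expect_error(mapPoseToMicrograph(pose, list()), "provenance")
})

test_that("angle recovery on clean crops stays below 4 degrees on average", {
  angles <- sampleAngles(list(family = "truncated-gaussian", mean = 90,
                              sd = 15), 150, seed = 71)
  rots <- sampleAngles(list(family = "uniform", min = 0, max = 180), 150,
                       seed = 72) * 2
  predPoses <- list(); gtPoses <- list()
  errs <- rep(NA_real_, length(angles))
  for (i in seq_along(angles)) {
    fx <- makeHingeCrop(angles[i], rotation = rots[i], seed = 1000 + i)
    id <- sprintf("c%03d", i)
    pose <- classicalPose(fx$crop, particleId = id)
    if (!poseComplete(pose)) next
    errs[i] <- abs(unname(poseAngles(pose)) - angles[i])
    predPoses[[id]] <- pose
    gtPoses[[id]] <- keypointPose(id, hingeSchema(), fx$gtPoseCrop@points)
  }
  expect_gt(mean(!is.na(errs)), 0.95)    # near-total pose success on clean crops
  expect_lte(mean(errs, na.rm = TRUE), 4)
  # the vertex is better localized than the tips, whose radial position
  # along the arm is poorly constrained
  sp <- spatialErrors(predPoses, gtPoses, nmPerPx = 1.4 / 3.92)
  expect_lte(sp$meanRadialError[["vertex"]],
             min(sp$meanRadialError[["tipA"]], sp$meanRadialError[["tipB"]]))
  expect_lte(sp$twoDimStd[["vertex"]],
             min(sp$twoDimStd[["tipA"]], sp$twoDimStd[["tipB"]]))
})

test_that("the nucleosome point is found near its blob under the extended schema", {
  cfg <- simulationConfig(noiseSd = 0.02, seed = 8)
  canvas <- matrix(cfg@backgroundLevel, 220, 220)
  rh <- renderHinge(canvas, 95, 20, c(110, 110), cfg)
  # attach a compact blob at the midpoint of arm A, offset outward
  tipA <- posePoint(rh$record$pose, "tipA")
  vert <- posePoint(rh$record$pose, "vertex")
  mid <- (tipA + vert) / 2
  dir <- (tipA - vert) / sqrt(sum((tipA - vert)^2))
  nucCtr <- mid + 12 * c(-dir[2], dir[1])
  px <- rh$pixels
  for (r in 1:220) for (cc in 1:220) {
    r2 <- (cc - 0.5 - nucCtr[1])^2 + (r - 0.5 - nucCtr[2])^2
    if (r2 < 200) px[r, cc] <- px[r, cc] + 0.4 * exp(-r2 / 30)
  }
  m <- Micrograph(pmin(pmax(px, 0), 1), cfg@nmPerPx)
  b <- rh$record$box
  side <- max(b["w"], b["h"]) + 30
  crop <- cropParticles(m, boundingBoxes(cx = b["cx"], cy = b["cy"],
                                         w = side, h = side), 200)[[1]]
  pose <- classicalPose(crop$image, hingeNucleosomeSchema())
  nuc <- posePoint(pose, "nucleosome")
  expect_true(all(is.finite(nuc)))
  mapped <- mapPoseToMicrograph(pose, crop$provenance)
  err <- sqrt(sum((posePoint(mapped, "nucleosome") - nucCtr)^2))
  expect_lt(err, 6)
})
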