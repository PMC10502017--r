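test_that("angle sampling respects the law, its support and the seed", {
  expect_length(sampleAngles(list(family = "uniform"), 0, seed = 1), 0)
  expect_equal(sampleAngles(list(family = "gaussian", mean = 90, sd = 0), 5,
                            seed = 3), rep(90, 5))
  a <- sampleAngles(list(family = "truncated-gaussian", mean = 90, sd = 15),
                    10000, seed = 5)
  expect_true(all(a >= 0 & a <= 180))
  # symmetric truncation about the mean: CLT bound on the sample mean
  expect_lt(abs(mean(a) - 90), 3 * 15 / sqrt(10000))
  expect_equal(a, sampleAngles(list(family = "truncated-gaussian", mean = 90,
                                    sd = 15), 10000, seed = 5))
  eh <- sampleAngles(list(family = "empirical-histogram",
                          edges = c(30, 60, 90), probs = c(1, 1)),
                     500, seed = 2)
  expect_true(all(eh >= 30 & eh <= 90))
  expect_error(sampleAngles(list(family = "nope"), 3, seed = 1), "unknown")
  expect_error(sampleAngles(list(family = "uniform", min = -5), 3, seed = 1),
               "support")
})

test_that("rendered hinges carry self-consistent ground truth", {
  cfg <- simulationConfig(seed = 1)
  canvas <- matrix(cfg@backgroundLevel, 260, 260)
  rh <- renderHinge(canvas, 90, 0, c(130, 130), cfg)
  expect_equal(unname(poseAngles(rh$record$pose)), 90, tolerance = 1e-9)
  rh2 <- renderHinge(canvas, 90, 137, c(130, 130), cfg)
  expect_equal(unname(poseAngles(rh2$record$pose)),
               unname(poseAngles(rh$record$pose)), tolerance = 1e-9)
  # the tight box contains every keypoint
  b <- rh$record$box
  pts <- rh$record$pose@points
  expect_true(all(pts$x >= b["cx"] - b["w"] / 2 - 1e-9 &
                  pts$x <= b["cx"] + b["w"] / 2 + 1e-9))
  expect_true(all(pts$y >= b["cy"] - b["h"] / 2 - 1e-9 &
                  pts$y <= b["cy"] + b["h"] / 2 + 1e-9))
  # arms are bright: the number of pixels lit to at least half the particle
  # intensity is about the geometric two-arm area, and the box region is
  # brighter on average than the untouched background
  lit <- rh$pixels > cfg@backgroundLevel + cfg@particleIntensity / 2
  armAreaPx <- 2 * (cfg@armLengthNm / cfg@nmPerPx) *
    (cfg@armWidthNm / cfg@nmPerPx)
  expect_gt(sum(lit), 0.8 * armAreaPx)
  rows <- max(1, floor(b["cy"] - b["h"] / 2)):min(260, ceiling(b["cy"] + b["h"] / 2))
  cols <- max(1, floor(b["cx"] - b["w"] / 2)):min(260, ceiling(b["cx"] + b["w"] / 2))
  expect_gt(mean(rh$pixels[rows, cols]) - cfg@backgroundLevel,
            cfg@particleIntensity * 0.1)
  expect_error(renderHinge(canvas, 90, 0, c(5, 5), cfg), "canvas")
})

test_that("micrograph generation honours counts, background and determinism", {
  empty <- simulationConfig(imageSize = 240, nTargetHinges = 0,
                            nVerticalDistractors = 0, nAggregates = 0,
                            nFreeBlobs = 0, seed = 2)
  g0 <- generateMicrograph(empty)
  expect_equal(nrow(g0$truth), 0)
  expect_lt(abs(mean(g0$micrograph@pixels) - empty@backgroundLevel), 0.05)

  cfg <- simulationConfig(imageSize = 700, nTargetHinges = 12,
                          nVerticalDistractors = 2, nAggregates = 1,
                          nFreeBlobs = 2, seed = 9)
  g <- generateMicrograph(cfg)
  expect_equal(sum(g$truth$class == "target_hinge"), 12)
  expect_length(g$poses, 12)
  g2 <- generateMicrograph(cfg)
  expect_identical(g$micrograph@pixels, g2$micrograph@pixels)
  expect_identical(g$truth, g2$truth)
  # angle recovery at source, for every target hinge
  for (id in names(g$poses)) {
    tr <- g$truth[g$truth$particle_id == id, ]
    expect_equal(unname(poseAngles(g$poses[[id]])), tr$angle,
                 tolerance = 1e-6)
  }
})

test_that("sampled angle distributions are faithful to their law", {
  law <- list(family = "truncated-gaussian", mean = 90, sd = 15)
  a <- sampleAngles(law, 10000, seed = 101)
  b <- sampleAngles(law, 10000, seed = 202)
  expect_gt(ksTwoSample(a, b)$pValue, 0.01)
})

test_that("dataset generation writes images, labels and a manifest that round-trip", {
  outDir <- withr::local_tempdir()
  cfg <- smallSimConfig(seed = 4)
  man0 <- generateDataset(cfg, 0, file.path(outDir, "empty"))
  expect_length(man0$images, 0)
  man <- generateDataset(cfg, 3, outDir)
  expect_length(man$images, 3)
  pngs <- list.files(outDir, pattern = "\\.png$")
  expect_length(pngs, 3)
  # labels round-trip through the YOLO reader at the written precision
  g1 <- generateMicrograph({cfg2 <- cfg; cfg2@seed <- man$images[[1]]$seed; cfg2})
  tgt <- g1$truth[g1$truth$class == "target_hinge", ]
  back <- readYoloLabels(file.path(outDir, man$images[[1]]$labels),
                         imageSize = cfg@imageSize)
  expect_equal(nrow(back), nrow(tgt))
  expect_equal(back$cx, tgt$cx, tolerance = 1e-5 * cfg@imageSize)
  expect_equal(back$w, tgt$w, tolerance = 1e-5 * cfg@imageSize)
  kp <- readKeypointCsv(file.path(outDir, "keypoints.csv"))
  expect_gt(length(kp), 0)
  expect_true(all(vapply(kp, poseComplete, logical(1))))
  expect_true(file.exists(file.path(outDir, "manifest.json")))
})
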