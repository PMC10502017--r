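test_that("IoU matching is greedy, one-to-one and confidence-ordered", {
  gt <- boundingBoxes(cx = c(10, 40), cy = c(10, 40), w = 8, h = 8)
  exact <- gt; exact$confidence <- c(0.5, 0.9)
  m <- matchDetections(exact, gt, 0.3)
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 0L, 0L))
  none <- matchDetections(boundingBoxes(), gt, 0.3)
  expect_equal(c(none$tp, none$fp, none$fn), c(0L, 0L, 2L))
  # two predictions on one truth: the one-to-one constraint makes one FP
  dup <- boundingBoxes(cx = c(10, 11), cy = c(10, 10), w = 8, h = 8,
                       confidence = c(0.9, 0.8))
  one <- boundingBoxes(cx = 10, cy = 10, w = 8, h = 8)
  m2 <- matchDetections(dup, one, 0.3)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1L, 1L, 0L))
  expect_equal(m2$matches$predIndex, 1L)  # higher confidence claims it
})

test_that("matching counts are invariant to permuting equal-confidence rows", {
  set.seed(61)
  gt <- boundingBoxes(cx = runif(6, 20, 200), cy = runif(6, 20, 200),
                      w = 20, h = 20)
  pred <- gt
  pred$cx <- pred$cx + runif(6, -4, 4)
  pred$confidence <- 0.8
  m1 <- matchDetections(pred, gt, 0.3)
  perm <- pred[sample(6), ]
  m2 <- matchDetections(perm, gt, 0.3)
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(m2$tp, m2$fp, m2$fn))
})

test_that("precision/recall/F1 reproduce the confusion arithmetic", {
  m <- precisionRecallF1(50, 10, 25)
  expect_equal(m$precision, 50 / 60)
  expect_equal(m$recall, 50 / 75)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  deg <- precisionRecallF1(0, 5, 3)
  expect_equal(deg$precision, 0)
  expect_equal(deg$recall, 0)
  expect_equal(deg$f1, 0)
  expect_true(deg$degenerate)
  noPred <- precisionRecallF1(0, 0, 3)
  expect_true(is.na(noPred$precision))
  expect_error(precisionRecallF1(0, 0, 0))
})

test_that("F1 lies between the harmonic bounds of precision and recall", {
  set.seed(62)
  for (i in 1:50) {
    tp <- sample(1:500, 1); fp <- sample(0:200, 1); fn <- sample(0:200, 1)
    m <- precisionRecallF1(tp, fp, fn)
    expect_lte(m$f1, min(1, 2 * min(m$precision, m$recall)))
    expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
  }
})

test_that("mean angle error averages absolute differences and ignores tip labels", {
  gt <- list(a = hingePoseFrom("a", c(0, 10), c(0, 0), c(10, 0)),
             b = hingePoseFrom("b", c(0, 10), c(0, 0), c(10, 0)))
  expect_equal(meanAngleError(gt, gt), 0)
  rot <- function(p, deg) c(cos(deg * pi / 180) * p[1] - sin(deg * pi / 180) * p[2],
                            sin(deg * pi / 180) * p[1] + cos(deg * pi / 180) * p[2])
  pred <- list(a = hingePoseFrom("a", rot(c(0, 10), 2), c(0, 0), c(10, 0)),
               b = hingePoseFrom("b", rot(c(0, 10), 6), c(0, 0), c(10, 0)))
  expect_equal(meanAngleError(pred, gt), 4, tolerance = 1e-9)
  swapped <- lapply(pred, function(p) {
    pts <- p@points
    pts[c(1, 3), c("x", "y")] <- pts[c(3, 1), c("x", "y")]
    keypointPose(p@particleId, p@schema, pts)
  })
  expect_equal(meanAngleError(swapped, gt), meanAngleError(pred, gt),
               tolerance = 1e-12)
  expect_error(meanAngleError(list(), gt), "no complete")
})

test_that("spatial errors separate bias from spread and count flips", {
  gt <- list(a = hingePoseFrom("a", c(0, 10), c(0, 0), c(10, 0)),
             b = hingePoseFrom("b", c(5, 25), c(5, 5), c(25, 5)))
  sp0 <- spatialErrors(gt, gt, nmPerPx = 1)
  expect_true(all(sp0$twoDimStd == 0))
  expect_equal(sp0$flipRate, 0)
  # constant offset on the vertex: pure bias, zero spread
  shifted <- lapply(gt, function(p) {
    pts <- p@points
    i <- pts$point == "vertex"
    pts$x[i] <- pts$x[i] + 3; pts$y[i] <- pts$y[i] + 4
    keypointPose(p@particleId, p@schema, pts)
  })
  sp1 <- spatialErrors(shifted, gt, nmPerPx = 1)
  v <- sp1$errors[sp1$errors$point == "vertex", ]
  expect_true(all(v$dx_nm == 3 & v$dy_nm == 4))
  expect_equal(sp1$twoDimStd[["vertex"]], 0)
  expect_equal(sp1$meanRadialError[["vertex"]], 5)
  expect_error(spatialErrors(gt, gt), "nmPerPx")
})

test_that("isotropic Gaussian noise gives 2D std sigma times sqrt(2)", {
  set.seed(63)
  n <- 2000; sigma <- 2
  gt <- list(); pred <- list()
  for (i in seq_len(n)) {
    id <- sprintf("p%04d", i)
    g <- hingePoseFrom(id, c(0, 30), c(0, 0), c(30, 0))
    pts <- g@points
    pts$x <- pts$x + rnorm(3, 0, sigma)
    pts$y <- pts$y + rnorm(3, 0, sigma)
    gt[[id]] <- g
    pred[[id]] <- keypointPose(id, g@schema, pts)
  }
  sp <- spatialErrors(pred, gt, nmPerPx = 1)
  for (nm in names(sp$twoDimStd))
    expect_lt(abs(sp$twoDimStd[[nm]] - sigma * sqrt(2)) / (sigma * sqrt(2)),
              0.05)
})

test_that("flip rate counts deliberate tip swaps", {
  gt <- list(); pred <- list()
  for (i in 1:10) {
    id <- sprintf("p%02d", i)
    g <- hingePoseFrom(id, c(0, 20), c(0, 0), c(20, 5))
    gt[[id]] <- g
    pts <- g@points
    if (i <= 4) pts[c(1, 3), c("x", "y")] <- pts[c(3, 1), c("x", "y")]
    pred[[id]] <- keypointPose(id, g@schema, pts)
  }
  sp <- spatialErrors(pred, gt, nmPerPx = 1)
  expect_equal(sp$flipRate, 0.4)
})
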