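# Internal helpers shared by the simulator and the classical backends.

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' All randomness in the package flows from one master seed; per-image and
#' per-stage seeds are derived by a stable string hash so that runs are
#' reproducible and stages are statistically independent.
#'
#' @param seed master seed (integer).
#' @param tag stage/image label.
#' @return an integer seed in \[0, 2^31 - 2\].
#' @export
deriveSeed <- function(seed, tag) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 131 + ch) %% m
  as.integer((((seed %% m) * 48271) %% m + h) %% m)
}

# 8-neighbour count of a logical matrix (used on skeletons).
.neighborCount <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(m)
  s <- matrix(0L, nr, nc)
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  for (dr in -1:1) for (dc in -1:1) if (dr != 0L || dc != 0L)
    s <- s + p[ri + dr, ci + dc]
  s
}

.thinMask <- function(mask) {
  storage.mode(mask) <- "integer"
  .thin_cpp(mask)
}

.label8 <- function(mask) {
  storage.mode(mask) <- "integer"
  .label8_cpp(mask)
}

# Total least squares line through (x, y): centroid + unit direction + RMS
# perpendicular residual (principal axis of the scatter).
.fitLinePCA <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  cxx <- mean(dx * dx); cyy <- mean(dy * dy); cxy <- mean(dx * dy)
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy)
  d <- c(cos(theta), sin(theta))
  resid <- -dx * d[2] + dy * d[1]
  list(point = c(mx, my), dir = d, rms = sqrt(mean(resid^2)))
}

# Distance from points to a segment [a, b].
.segDist <- function(px, py, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- pmin(pmax(((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2, 0), 1)
  sqrt((px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2)
}

# Matrix-index coordinates of foreground pixels as continuous 0-based
# (x, y) pixel centres.
.maskCoords <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  list(x = c - 0.5, y = r - 0.5, row = r, col = c)
}

# Total-least-squares residual sum of squares from raw moments
# (n, sum x, sum y, sum x^2, sum y^2, sum xy).
.tlsSse <- function(n, sx, sy, sxx, syy, sxy) {
  cxx <- sxx - sx^2 / n; cyy <- syy - sy^2 / n; cxy <- sxy - sx * sy / n
  (cxx + cyy) / 2 - sqrt(((cxx - cyy) / 2)^2 + cxy^2)
}

# One-pass outlier-trimmed TLS line fit: fit, drop points with perpendicular
# residual above max(2, 2.5 * rms), refit. Robust to short skeleton
# artifacts (e.g. runs along a crop border) polluting an arm.
.fitLineTrimmed <- function(x, y) {
  fit <- .fitLinePCA(x, y)
  res <- abs(-(x - fit$point[1]) * fit$dir[2] + (y - fit$point[2]) * fit$dir[1])
  keep <- res <= max(2, 2.5 * fit$rms)
  if (sum(keep) >= 5 && any(!keep)) fit <- .fitLinePCA(x[keep], y[keep])
  fit$keepFrac <- mean(keep)
  fit
}

# Two-arm skeleton analysis of a binary particle mask.
#
# The mask is thinned and the skeleton's longest geodesic path extracted;
# for a two-arm particle this path runs tip -> vertex -> tip while ignoring
# short spurs and junction clutter. The path is split at the index
# minimizing the total TLS residual of two line fits (computed in O(n) from
# prefix moments); each arm is then re-fitted excluding pixels near the
# split (where thinning rounds the corner), with one outlier-trimming pass.
# The vertex is refined as the intersection of the two arm lines and the
# tips are the path endpoints projected onto them.
#
# Returns (coordinates 0-based, in the mask frame):
#   ok = TRUE: vertex, tips (list of 2), dirs, rms (per-arm fit RMS, px),
#              branchLen (path pixels per arm), keepFrac, skelLength
#   ok = FALSE, rod = TRUE: the path is straight (single segment): line fit
#              and projected ends
#   ok = FALSE, rod = FALSE: analysis failed
.analyzeTwoArm <- function(mask, minBranchLen = 8, excludeRadius = NULL,
                           excludeFactor = 1.5, borderMargin = 0,
                           rodRms = 1.2) {
  # borderMargin = NULL: scale the border exclusion with the stroke width
  fail <- list(ok = FALSE, rod = FALSE)
  if (sum(mask) < 10) return(fail)
  skel <- .thinMask(mask)
  nSkel <- sum(skel)
  if (nSkel < 5) return(fail)
  strokeW <- sum(mask) / nSkel
  if (is.null(excludeRadius))
    excludeRadius <- max(3, excludeFactor * strokeW)
  if (is.null(borderMargin)) borderMargin <- max(6, 0.75 * strokeW)
  storage.mode(skel) <- "integer"
  path <- .diameter_path_cpp(skel)
  n <- nrow(path)
  if (n < max(10, 2 * minBranchLen)) return(fail)
  x <- path[, 2] - 0.5; y <- path[, 1] - 0.5
  whole <- .fitLinePCA(x, y)
  if (whole$rms <= rodRms) {
    t <- (x - whole$point[1]) * whole$dir[1] + (y - whole$point[2]) * whole$dir[2]
    ends <- list(whole$point + min(t) * whole$dir,
                 whole$point + max(t) * whole$dir)
    return(list(ok = FALSE, rod = TRUE, line = whole, ends = ends,
                skelLength = nSkel))
  }
  # optimal split of the path into two straight segments
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x^2); cyy <- cumsum(y^2); cxy <- cumsum(x * y)
  lo <- max(3L, as.integer(minBranchLen))
  hi <- n - lo
  if (hi <= lo) return(fail)
  ks <- lo:hi
  sseL <- .tlsSse(ks, cx[ks], cy[ks], cxx[ks], cyy[ks], cxy[ks])
  nR <- n - ks
  sseR <- .tlsSse(nR, cx[n] - cx[ks], cy[n] - cy[ks], cxx[n] - cxx[ks],
                  cyy[n] - cyy[ks], cxy[n] - cxy[ks])
  k <- ks[which.min(sseL + sseR)]
  split <- c(x[k], y[k])
  sides <- list(seq_len(k), (k + 1L):n)
  fits <- vector("list", 2)
  # where an arm is cut by the image/crop border the skeleton follows the
  # cut, not the arm: drop path pixels near the border from the fits
  inner <- rep(TRUE, n)
  if (borderMargin > 0)
    inner <- x >= borderMargin & x <= ncol(mask) - borderMargin &
      y >= borderMargin & y <= nrow(mask) - borderMargin
  for (i in 1:2) {
    ix <- sides[[i]]
    d <- sqrt((x[ix] - split[1])^2 + (y[ix] - split[2])^2)
    keep <- d >= excludeRadius & inner[ix]
    if (sum(keep) < 5) keep <- d >= excludeRadius
    if (sum(keep) < 5) keep <- rep(TRUE, length(ix))
    fits[[i]] <- .fitLineTrimmed(x[ix][keep], y[ix][keep])
    endIx <- if (i == 1) 1L else n
    tipPix <- c(x[endIx], y[endIx])
    if (sum((tipPix - split) * fits[[i]]$dir) < 0)
      fits[[i]]$dir <- -fits[[i]]$dir
    tt <- sum((tipPix - fits[[i]]$point) * fits[[i]]$dir)
    fits[[i]]$tip <- fits[[i]]$point + tt * fits[[i]]$dir
    fits[[i]]$len <- length(ix)
  }
  d1 <- fits[[1]]$dir; d2 <- fits[[2]]$dir
  p1 <- fits[[1]]$point; p2 <- fits[[2]]$point
  det <- d1[1] * (-d2[2]) - (-d2[1]) * d1[2]
  vertex <- split
  if (abs(det) > 1e-8) {
    rhs <- p2 - p1
    t1 <- (rhs[1] * (-d2[2]) - (-d2[1]) * rhs[2]) / det
    cand <- p1 + t1 * d1
    # reject wild intersections of near-parallel fits
    if (sqrt(sum((cand - split)^2)) <= max(10, 2 * excludeRadius))
      vertex <- cand
  }
  dirs <- list(d1, d2)
  tips <- list(fits[[1]]$tip, fits[[2]]$tip)
  for (i in 1:2)
    if (sum((tips[[i]] - vertex) * dirs[[i]]) < 0) dirs[[i]] <- -dirs[[i]]
  list(ok = TRUE, vertex = vertex, tips = tips, dirs = dirs,
       rms = c(fits[[1]]$rms, fits[[2]]$rms),
       branchLen = c(fits[[1]]$len, fits[[2]]$len),
       keepFrac = c(fits[[1]]$keepFrac, fits[[2]]$keepFrac),
       skelLength = nSkel)
}

# Fraction of mask pixels lying within halfWidth of any of the given
# segments (each segment a list(a, b) of 0-based coordinates).
.segmentCoverage <- function(mask, segments, halfWidth) {
  co <- .maskCoords(mask)
  if (!length(co$x)) return(0)
  dmin <- rep(Inf, length(co$x))
  for (s in segments)
    dmin <- pmin(dmin, .segDist(co$x, co$y, s[[1]], s[[2]]))
  mean(dmin <= halfWidth)
}

.normalizeImage <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi <= lo) return(NULL)
  (m - lo) / (hi - lo)
}

.otsu <- function(m) {
  EBImage::otsu(EBImage::Image(pmin(pmax(m, 0), 1)), range = c(0, 1))
}
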