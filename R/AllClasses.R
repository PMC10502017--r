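#' Micrograph: a calibrated grayscale electron micrograph
#'
#' Pixel intensities are stored as a numeric matrix with rows = image rows
#' (y, increasing downward) and columns = image columns (x). Coordinates used
#' throughout the package are continuous, 0-based, origin at the top-left
#' corner; the centre of pixel `[i, j]` (1-based matrix indices) is at
#' `(x, y) = (j - 0.5, i - 0.5)`.
#'
#' @slot pixels numeric matrix of finite intensities (typically in \[0, 1\]).
#' @slot nmPerPx nanometres per pixel; positive spatial calibration.
#' @aliases Micrograph-class
#' @exportClass Micrograph
setClass("Micrograph",
  representation(pixels = "matrix", nmPerPx = "numeric"),
  validity = function(object) {
    if (!is.numeric(object@pixels)) return("pixels must be numeric")
    if (any(!is.finite(object@pixels))) return("pixel intensities must be finite")
    if (length(object@nmPerPx) != 1L || !is.finite(object@nmPerPx) ||
        object@nmPerPx <= 0) return("nmPerPx must be a single positive number")
    TRUE
  })

#' Construct a Micrograph
#'
#' @param pixels numeric matrix (rows = y, cols = x).
#' @param nmPerPx nanometres per pixel (default 1.4, chosen so a 50 px hinge
#'   arm corresponds to ~70 nm at the 960-px working scale).
#' @return a [Micrograph-class] object.
#' @export
Micrograph <- function(pixels, nmPerPx = 1.4) {
  new("Micrograph", pixels = pixels, nmPerPx = nmPerPx)
}

#' @describeIn Micrograph image width in pixels.
#' @param x a `Micrograph`.
#' @export
imageWidth <- function(x) ncol(x@pixels)

#' @describeIn Micrograph image height in pixels.
#' @export
imageHeight <- function(x) nrow(x@pixels)

setMethod("show", "Micrograph", function(object) {
  cat(sprintf("Micrograph: %d x %d px, %.3g nm/px, intensity [%.3g, %.3g]\n",
              ncol(object@pixels), nrow(object@pixels), object@nmPerPx,
              min(object@pixels), max(object@pixels)))
})

#' DeviceSchema: named keypoints and angle definitions for a device
#'
#' A schema declares which named keypoints a device has, which ordered
#' triples (tip, vertex, tip) define its angles, and which points are
#' tracked as positions only (e.g. a nucleosome blob).
#'
#' @slot name device name.
#' @slot keypointNames ordered character vector of unique keypoint names.
#' @slot angleDefs list of length-3 character vectors `(tip1, vertex, tip2)`.
#' @slot positionPoints character vector of position-only point names.
#' @aliases DeviceSchema-class
#' @exportClass DeviceSchema
setClass("DeviceSchema",
  representation(name = "character", keypointNames = "character",
                 angleDefs = "list", positionPoints = "character"),
  validity = function(object) {
    kp <- object@keypointNames
    if (anyDuplicated(kp)) return("keypoint names must be unique")
    for (ad in object@angleDefs) {
      if (length(ad) != 3L) return("each angle definition needs 3 point names")
      if (!all(ad %in% kp)) return("angle definition names must be keypoints")
    }
    if (!all(object@positionPoints %in% kp))
      return("position points must be keypoints")
    TRUE
  })

#' Construct a DeviceSchema
#'
#' @param name device name.
#' @param keypointNames ordered keypoint names.
#' @param angleDefs list of `(tip1, vertex, tip2)` name triples.
#' @param positionPoints names tracked as positions only.
#' @return a [DeviceSchema-class].
#' @export
deviceSchema <- function(name, keypointNames, angleDefs = list(),
                         positionPoints = character()) {
  new("DeviceSchema", name = name, keypointNames = keypointNames,
      angleDefs = angleDefs, positionPoints = positionPoints)
}

setMethod("show", "DeviceSchema", function(object) {
  cat(sprintf("DeviceSchema '%s': points [%s], %d angle(s)\n", object@name,
              paste(object@keypointNames, collapse = ", "),
              length(object@angleDefs)))
})

#' KeypointPose: named keypoints with confidences for one particle
#'
#' Points are stored as a data.frame with columns `point`, `x`, `y`,
#' `confidence`; a missing keypoint has `NA` coordinates and confidence 0.
#' Coordinates follow the package convention (0-based, y down), in whatever
#' frame the pose was produced in (crop or micrograph).
#'
#' @slot particleId identifier of the particle.
#' @slot schema the [DeviceSchema-class] the pose conforms to.
#' @slot points data.frame `point, x, y, confidence`.
#' @aliases KeypointPose-class
#' @exportClass KeypointPose
setClass("KeypointPose",
  representation(particleId = "character", schema = "DeviceSchema",
                 points = "data.frame"),
  validity = function(object) {
    p <- object@points
    need <- c("point", "x", "y", "confidence")
    if (!all(need %in% names(p))) return("points needs point,x,y,confidence")
    if (!setequal(p$point, object@schema@keypointNames))
      return("points must cover exactly the schema keypoints")
    cf <- p$confidence
    if (any(!is.finite(cf)) || any(cf < 0 | cf > 1))
      return("confidences must lie in [0,1]")
    miss <- !is.finite(p$x) | !is.finite(p$y)
    if (any(cf[miss] > 0)) return("missing points must have confidence 0")
    TRUE
  })

#' Construct a KeypointPose
#'
#' @param particleId particle identifier.
#' @param schema a [DeviceSchema-class].
#' @param points data.frame with columns `point, x, y, confidence`. Keypoints
#'   absent from `points` are added as missing (NA coordinates, confidence 0).
#' @return a [KeypointPose-class].
#' @export
keypointPose <- function(particleId, schema, points) {
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  absent <- setdiff(schema@keypointNames, points$point)
  if (length(absent)) {
    points <- rbind(points[, c("point", "x", "y", "confidence")],
                    data.frame(point = absent, x = NA_real_, y = NA_real_,
                               confidence = 0))
  }
  points <- points[match(schema@keypointNames, points$point), , drop = FALSE]
  rownames(points) <- NULL
  new("KeypointPose", particleId = as.character(particleId), schema = schema,
      points = points)
}

#' @describeIn keypointPose coordinates of one named keypoint as `c(x, y)`.
#' @param pose a `KeypointPose`.
#' @param name keypoint name.
#' @export
posePoint <- function(pose, name) {
  i <- match(name, pose@points$point)
  if (is.na(i)) stop("unknown keypoint '", name, "'")
  c(x = pose@points$x[i], y = pose@points$y[i])
}

#' @describeIn keypointPose confidence of one named keypoint.
#' @export
poseConfidence <- function(pose, name) {
  i <- match(name, pose@points$point)
  if (is.na(i)) stop("unknown keypoint '", name, "'")
  pose@points$confidence[i]
}

#' @describeIn keypointPose TRUE if all schema keypoints have coordinates.
#' @export
poseComplete <- function(pose) {
  all(is.finite(pose@points$x) & is.finite(pose@points$y))
}

setMethod("show", "KeypointPose", function(object) {
  cat(sprintf("KeypointPose '%s' (%s): %d/%d points present\n",
              object@particleId, object@schema@name,
              sum(is.finite(object@points$x)), nrow(object@points)))
})

#' AngleDistribution: binned angular probability over \[0, 180\] degrees
#'
#' @slot binEdges monotone bin edges covering \[0, 180\] degrees.
#' @slot probabilities per-bin probabilities (non-negative, sum to 1).
#' @slot nSamples number of angle observations binned.
#' @aliases AngleDistribution-class
#' @exportClass AngleDistribution
setClass("AngleDistribution",
  representation(binEdges = "numeric", probabilities = "numeric",
                 nSamples = "numeric"),
  validity = function(object) {
    e <- object@binEdges
    p <- object@probabilities
    if (length(p) != length(e) - 1L) return("need length(edges) = bins + 1")
    if (any(diff(e) <= 0)) return("bin edges must increase")
    if (abs(e[1]) > 1e-9 || abs(e[length(e)] - 180) > 1e-9)
      return("bins must cover [0, 180] degrees")
    if (any(p < 0)) return("probabilities must be non-negative")
    if (abs(sum(p) - 1) > 1e-9) return("probabilities must sum to 1")
    TRUE
  })

#' @describeIn anglesToDistribution bin centres of a distribution or landscape.
#' @param x an `AngleDistribution` or `FreeEnergyLandscape`.
#' @export
binCenters <- function(x) {
  if (is(x, "AngleDistribution")) {
    e <- x@binEdges
    (e[-1] + e[-length(e)]) / 2
  } else x@binCenters
}

setMethod("show", "AngleDistribution", function(object) {
  cat(sprintf("AngleDistribution: %d bins of %.3g deg, n = %d\n",
              length(object@probabilities), diff(object@binEdges[1:2]),
              as.integer(object@nSamples)))
})

#' FreeEnergyLandscape: Boltzmann-inverted angular free energy and torque
#'
#' Energies are in units of kT, shifted so the minimum over defined bins is
#' zero; bins with zero observed probability are undefined (`NA`), not zero.
#' Torque is the negative energy gradient in kT/degree at the bin centres.
#'
#' @slot binCenters degrees.
#' @slot energy kT per bin; `NA` where the probability was zero.
#' @slot torque kT/degree per bin; `NA` where undefined.
#' @slot referenceOffset the subtracted offset in kT (min of the raw -kT ln p).
#' @slot kT energy unit used.
#' @aliases FreeEnergyLandscape-class
#' @exportClass FreeEnergyLandscape
setClass("FreeEnergyLandscape",
  representation(binCenters = "numeric", energy = "numeric",
                 torque = "numeric", referenceOffset = "numeric",
                 kT = "numeric"),
  validity = function(object) {
    if (length(object@energy) != length(object@binCenters))
      return("energy and binCenters lengths differ")
    def <- object@energy[is.finite(object@energy)]
    if (length(def) && abs(min(def)) > 1e-9)
      return("minimum defined energy must be 0")
    TRUE
  })

setMethod("show", "FreeEnergyLandscape", function(object) {
  def <- sum(is.finite(object@energy))
  cat(sprintf(
    "FreeEnergyLandscape: %d/%d bins defined, max %.3g kT, offset %.3g kT\n",
    def, length(object@energy),
    if (def) max(object@energy, na.rm = TRUE) else NA_real_,
    object@referenceOffset))
})
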