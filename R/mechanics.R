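#' Bin measured angles into an angular probability distribution
#'
#' Histogram over \[0, 180\] degrees with right-open bins
#' `[e_i, e_{i+1})`, except the last bin which is closed at 180.
#'
#' @param angles angles in degrees, all in \[0, 180\].
#' @param binWidth bin width in degrees; must divide 180 (default 5).
#' @return an [AngleDistribution-class].
#' @export
anglesToDistribution <- function(angles, binWidth = 5) {
  if (!length(angles)) stop("empty angle list: distribution undefined")
  if (any(!is.finite(angles)) || any(angles < 0 | angles > 180))
    stop("all angles must lie in [0, 180] degrees")
  nb <- 180 / binWidth
  if (abs(nb - round(nb)) > 1e-9) stop("binWidth must divide 180")
  nb <- as.integer(round(nb))
  edges <- (0:nb) * binWidth
  bin <- pmin(floor(angles / binWidth) + 1L, nb) # 180 falls in the last bin
  counts <- tabulate(bin, nb)
  new("AngleDistribution", binEdges = edges,
      probabilities = counts / length(angles),
      nSamples = length(angles))
}

#' Boltzmann inversion of an angular distribution
#'
#' Converts per-bin probabilities into a free-energy landscape:
#' `E_i = -kT * ln(p_i)` for `p_i > 0`, shifted so the minimum defined
#' energy is zero (the subtracted offset is recorded). Bins with zero
#' probability are left undefined (`NA`) rather than imputed; pass
#' `pseudocount > 0` to add that many counts to every bin first if a fully
#' defined landscape is required.
#'
#' @param dist an [AngleDistribution-class].
#' @param kT energy unit (default 1, i.e. energies in kT).
#' @param pseudocount counts added to every bin before inversion (default 0).
#' @return a [FreeEnergyLandscape-class] (torque slot `NA`; see
#'   [torqueFromEnergy()]).
#' @export
boltzmannInvert <- function(dist, kT = 1, pseudocount = 0) {
  p <- dist@probabilities
  if (pseudocount > 0) {
    counts <- p * dist@nSamples + pseudocount
    p <- counts / sum(counts)
  }
  if (all(p <= 0)) stop("all-zero distribution cannot be inverted")
  E <- ifelse(p > 0, -kT * log(p), NA_real_)
  offset <- min(E, na.rm = TRUE)
  new("FreeEnergyLandscape", binCenters = binCenters(dist),
      energy = E - offset, torque = rep(NA_real_, length(E)),
      referenceOffset = offset, kT = kT)
}

#' Torque profile from a free-energy landscape
#'
#' The torque is the negative energy gradient, `tau = -dE/dtheta`, in
#' kT/degree, estimated by central finite differences over each contiguous
#' run of defined bins (one-sided differences at run boundaries). Where the
#' energy is undefined the torque is `NA`. Sign convention: energy
#' increasing with angle gives negative torque (restoring toward smaller
#' angles).
#'
#' @param landscape a [FreeEnergyLandscape-class] with at least two
#'   contiguous defined bins.
#' @return numeric vector of torques at the bin centres.
#' @export
torqueFromEnergy <- function(landscape) {
  E <- landscape@energy
  theta <- landscape@binCenters
  def <- which(is.finite(E))
  if (length(def) < 2) stop("need at least 2 defined energy bins")
  tau <- rep(NA_real_, length(E))
  runs <- split(def, cumsum(c(1, diff(def) != 1)))
  anyRun <- FALSE
  for (run in runs) {
    n <- length(run)
    if (n < 2) next
    anyRun <- TRUE
    i <- run
    g <- numeric(n)
    if (n == 2) {
      g[] <- (E[i[2]] - E[i[1]]) / (theta[i[2]] - theta[i[1]])
    } else {
      g[2:(n - 1)] <- (E[i[3:n]] - E[i[1:(n - 2)]]) /
        (theta[i[3:n]] - theta[i[1:(n - 2)]])
      g[1] <- (E[i[2]] - E[i[1]]) / (theta[i[2]] - theta[i[1]])
      g[n] <- (E[i[n]] - E[i[n - 1]]) / (theta[i[n]] - theta[i[n - 1]])
    }
    tau[i] <- -g
  }
  if (!anyRun) stop("no contiguous run of >= 2 defined bins")
  tau
}

#' Curvature of a free-energy landscape by weighted quadratic fit
#'
#' Fits `E = a * theta^2 + b * theta + c` over the defined bins by least
#' squares (optionally weighted, e.g. by bin counts) and returns the second
#' derivative `2a` in kT/deg^2. For angles distributed as a Gaussian with
#' standard deviation sigma the analytic curvature is `kT / sigma^2`, so
#' this recovers the torsional stiffness.
#'
#' @param landscape a [FreeEnergyLandscape-class].
#' @param weights optional per-bin fit weights (defaults to equal weights on
#'   defined bins).
#' @return curvature `d2E/dtheta2` in kT/degree^2.
#' @export
landscapeCurvature <- function(landscape, weights = NULL) {
  def <- is.finite(landscape@energy)
  if (sum(def) < 3) stop("need at least 3 defined bins for a quadratic fit")
  th <- landscape@binCenters[def]
  E <- landscape@energy[def]
  w <- if (is.null(weights)) rep(1, sum(def)) else weights[def]
  fit <- lm(E ~ th + I(th^2), weights = w)
  2 * unname(coef(fit)[["I(th^2)"]])
}

#' Two-sample Kolmogorov-Smirnov test between angle samples
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' uses the standard asymptotic two-sample KS distribution with effective
#' sample size `n_a * n_b / (n_a + n_b)` (adequate for the hundreds of
#' particles typical here). The null hypothesis is that the two angle
#' arrays come from the same continuous distribution.
#'
#' @param a,b non-empty numeric samples (degrees).
#' @return list with `statistic` (D) and `pValue`.
#' @export
ksTwoSample <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), pValue = unname(kt$p.value))
}
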