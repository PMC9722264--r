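#' Weighted polar distribution of propagation directions
#'
#' Pools all valid per-pixel velocity vectors (across animals when given a
#' list of fields), bins the directions over (-pi, pi], each vector
#' contributing its speed as weight, and normalizes to unit mass.
#'
#' @param x a [VelocityField-class], a list of them, or a numeric vector of
#'   angles (rad).
#' @param weights weights for numeric-angle input (e.g. speeds); default 1.
#' @param nBins number of angular bins, default 36.
#' @return a [PolarDistribution-class].
#' @export
weightedPolarDistribution <- function(x, weights = NULL, nBins = 36) {
  if (is(x, "VelocityField")) x <- list(x)
  if (is.list(x)) {
    angles <- unlist(lapply(x, function(f) directions(f)[validMask(f)]))
    weights <- unlist(lapply(x, function(f) speeds(f)[validMask(f)]))
  } else {
    angles <- as.numeric(x)
    if (is.null(weights)) weights <- rep(1, length(angles))
  }
  if (!length(angles)) stop("no valid vectors")
  if (all(weights == 0)) stop("all weights are zero")
  angles <- wrapAngle(angles)
  edges <- seq(-pi, pi, length.out = nBins + 1)
  idx <- pmin(pmax(ceiling((angles + pi) / (2 * pi) * nBins), 1L), nBins)
  mass <- vapply(seq_len(nBins), function(b) sum(weights[idx == b]), numeric(1))
  mass <- mass / sum(mass)
  new("PolarDistribution", binEdges = edges, mass = mass,
      angles = angles, weights = weights)
}

#' Weighted two-sample Kuiper statistic
#'
#' `V = max(F_A - F_B) + max(F_B - F_A)` over the circle, with `F` the
#' weighted empirical CDFs; rotation-invariant by construction. Reduces to
#' the classical unweighted Kuiper statistic for equal weights.
#'
#' @param anglesA,anglesB sample angles (rad).
#' @param weightsA,weightsB nonnegative weights; default 1.
#' @return the statistic V in [0, 2].
#' @export
kuiperStatistic <- function(anglesA, anglesB, weightsA = NULL, weightsB = NULL) {
  if (!length(anglesA) || !length(anglesB)) stop("both samples must be non-empty")
  if (is.null(weightsA)) weightsA <- rep(1, length(anglesA))
  if (is.null(weightsB)) weightsB <- rep(1, length(anglesB))
  if (sum(weightsA) <= 0 || sum(weightsB) <= 0) stop("all weights are zero")
  a <- wrapAngle(anglesA); b <- wrapAngle(anglesB)
  ang <- c(a, b)
  ## signed ECDF increments of d(theta) = F_A(theta) - F_B(theta)
  inc <- c(weightsA / sum(weightsA), -weightsB / sum(weightsB))
  o <- order(ang)
  d <- cumsum(inc[o])
  ## with tied angles, d is the value after all increments at that angle
  dv <- d[!duplicated(ang[o], fromLast = TRUE)]
  max(dv, 0) + max(-dv, 0)
}

#' Two-sample Kuiper test with permutation significance
#'
#' The weighted Kuiper statistic is compared against a permutation null built
#' by relabelling the pooled (angle, weight) pairs; with `unitsA`/`unitsB`
#' given, whole units (e.g. animals) are swapped instead of single vectors,
#' respecting within-animal dependence of pixel vectors.
#'
#' @param anglesA,anglesB sample angles (rad).
#' @param weightsA,weightsB nonnegative weights (speeds); default 1.
#' @param nPerm number of permutations, default 5000.
#' @param seed optional RNG seed.
#' @param unitsA,unitsB optional unit (animal) labels per observation; when
#'   supplied, permutation swaps whole units between groups.
#' @return list(V, p, nPerm).
#' @export
kuiperTwoSample <- function(anglesA, anglesB, weightsA = NULL, weightsB = NULL,
                            nPerm = 5000, seed = NULL,
                            unitsA = NULL, unitsB = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(weightsA)) weightsA <- rep(1, length(anglesA))
  if (is.null(weightsB)) weightsB <- rep(1, length(anglesB))
  vObs <- kuiperStatistic(anglesA, anglesB, weightsA, weightsB)
  ang <- c(anglesA, anglesB)
  wts <- c(weightsA, weightsB)
  nA <- length(anglesA)
  byUnit <- !is.null(unitsA) && !is.null(unitsB)
  if (byUnit) {
    unit <- c(paste0("A.", unitsA), paste0("B.", unitsB))
    uLev <- unique(unit)
    nUnitsA <- length(unique(unitsA))
  }
  exceed <- 0L
  for (k in seq_len(nPerm)) {
    if (byUnit) {
      pick <- sample(uLev, nUnitsA)
      inA <- unit %in% pick
    } else {
      idx <- sample.int(length(ang), nA)
      inA <- logical(length(ang)); inA[idx] <- TRUE
    }
    if (!any(inA) || all(inA)) next
    vP <- kuiperStatistic(ang[inA], ang[!inA], wts[inA], wts[!inA])
    if (vP >= vObs - 1e-12) exceed <- exceed + 1L
  }
  list(V = vObs, p = (1 + exceed) / (nPerm + 1), nPerm = nPerm)
}
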