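## shared fixture builders; everything is generated in code at test time

emptyEvents <- function() {
  data.frame(time = numeric(), originAp = numeric(), originMl = numeric(),
             speedMmS = numeric(), directionRad = numeric(),
             evoked = logical(), stimIndex = integer())
}

## a GroundTruth with no events (used to drive PA renderers)
emptyGroundTruth <- function(config, geometry = fieldGeometry(),
                             stimuli = NULL) {
  st <- if (is.null(stimuli)) data.frame() else
    data.frame(onsetS = onsets(stimuli), modality = modality(stimuli))
  new("GroundTruth", events = emptyEvents(),
      siteOnsets = stats::setNames(
        rep(list(numeric()), nrow(geometry@sites)), rownames(geometry@sites)),
      stimuli = st, nMerged = 0L, geometry = geometry, config = config,
      empty = TRUE)
}

## a GroundTruth holding exactly the given wave events
wavesGroundTruth <- function(events, config, geometry = fieldGeometry()) {
  new("GroundTruth", events = events,
      siteOnsets = cortexwaves:::computeSiteOnsets(events, geometry),
      stimuli = data.frame(), nMerged = 0L, geometry = geometry,
      config = config, empty = nrow(events) == 0L)
}

## one plane wave starting at (ap, ml) at time t, moving along direction
singleWave <- function(t = 3, ap = -3.8, ml = 2.0, speed = 30.5, dir = 0) {
  data.frame(time = t, originAp = ap, originMl = ml, speedMmS = speed,
             directionRad = dir, evoked = FALSE, stimIndex = NA_integer_)
}

## ground-truth EventList (for matching detected events against the truth)
truthEventList <- function(onsets, site = "S1") {
  new("EventList",
      events = data.frame(onsetS = onsets, peakS = onsets,
                          amplitude = rep(1, length(onsets)),
                          durationS = rep(1, length(onsets))),
      site = site)
}

## raw photometry trace object around a baseline of 100
rawTrace <- function(x, fs = 2000, site = "S1", state = "unknown") {
  new("PhotometryTrace", samples = x, fsHz = fs, site = site,
      stateLabel = state, units = "raw")
}

dffTrace <- function(x, fs = 2000, site = "S1", state = "unknown") {
  new("PhotometryTrace", samples = x, fsHz = fs, site = site,
      stateLabel = state, units = "dff")
}

## standard detection pipeline: df/f, 20-Hz Gaussian low-pass, detect
detectPipeline <- function(trace, ...) {
  d <- lowpassGaussian(normalizeDff(trace, pickBaselineWindow(trace)))
  detectEvents(d, ...)
}

## brute-force O(n^2) two-sample Kuiper oracle: recompute the statistic from
## scratch for a rotation origin placed at every data angle; returns the
## range over origins (rotation invariance makes it constant)
kuiperOracle <- function(a, b) {
  pool <- sort(c(a, b))
  vs <- vapply(pool, function(orig) {
    ar <- sort((a - orig) %% (2 * pi))
    br <- sort((b - orig) %% (2 * pi))
    pts <- sort(c(ar, br))
    fA <- vapply(pts, function(t) mean(ar <= t), numeric(1))
    fB <- vapply(pts, function(t) mean(br <= t), numeric(1))
    d <- fA - fB
    max(d, 0) + max(-d, 0)
  }, numeric(1))
  vs
}

## direct-scan oracle for the refractory estimator definition
refractoryOracle <- function(intervals, success, binS = 0.5, criterion = 0.9) {
  ok <- !is.na(intervals)
  intervals <- intervals[ok]; success <- success[ok]
  b <- 0
  while (b * binS <= max(intervals)) {
    inBin <- intervals >= b * binS & intervals < (b + 1) * binS
    if (any(inBin) && mean(success[inBin]) > criterion) return(b * binS)
    b <- b + 1
  }
  NA_real_
}
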