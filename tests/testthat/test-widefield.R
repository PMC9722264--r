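## small square geometry used for rotation tests
squareGeometry <- function(n = 40, pitch = 0.1) {
  fieldGeometry(apLim = c(0, -n * pitch), mlLim = c(0, n * pitch),
                pixelPitchMm = pitch,
                sites = matrix(numeric(0), 0, 2,
                               dimnames = list(NULL, c("ap", "ml"))))
}

## synthetic movie with a given per-frame pixel generator
movieFrom <- function(f, frameRate = 20, geom = squareGeometry(), t0 = 0,
                      units = "raw") {
  new("CalciumMovie", frames = f, frameRateHz = frameRate, t0S = t0,
      geometry = geom, units = units, aligned = TRUE)
}

test_that("df/f conversion uses the frame before the stimulus", {
  geom <- squareGeometry(4)
  f <- array(100, c(10, 4, 4))
  f[6:10, , ] <- 110
  mov <- movieFrom(f, frameRate = 10, geom = geom)
  ## frame times 0, .1, ..., .9; the frame before 0.52 s is frame 6 (t = .5)
  d <- dffMovie(mov, 0.52)
  expect_equal(frames(d)[7, 1, 1], 0)   # 110 vs F0 = 110
  d2 <- dffMovie(mov, 0.45)             # F0 = frame 5 (t = .4) = 100
  expect_equal(frames(d2)[6, 1, 1], 10) # 10 %df/f
  expect_true(all(frames(dffMovie(movieFrom(array(100, c(5, 4, 4)),
                                            10, geom), 0.25)) == 0))
  fz <- f; fz[3, 1, 1] <- 0
  expect_warning(dz <- dffMovie(movieFrom(fz, 10, geom), 0.25), "masked")
  expect_true(all(is.na(frames(dz)[, 1, 1])))
})

test_that("stimulus-triggered averages average aligned df/f segments", {
  geom <- squareGeometry(4)
  oneSeg <- array(100, c(300, 4, 4))
  for (s in c(50, 150, 250)) oneSeg[s + (2:10), , ] <- 120
  mov <- movieFrom(oneSeg, frameRate = 10, geom = geom)
  stim <- c(50, 150, 250) / 10 + 0.05
  sta <- stimulusTriggeredAverage(mov, stim, windowS = c(-1, 2))
  expect_equal(sta$nUsed, 3L)
  ## identical segments: average equals any single segment
  expect_equal(max(frames(sta$stack)), 20)
  expect_equal(min(frames(sta$stack)), 0)
  ## i.i.d. noise: pixel SD shrinks like 1/sqrt(n)
  set.seed(1)
  noisy <- array(100 + rnorm(3000 * 16, 0, 5), c(3000, 4, 4))
  movN <- movieFrom(noisy, frameRate = 10, geom = geom)
  stimN <- seq(20, 280, by = 10)
  staN <- stimulusTriggeredAverage(movN, stimN, windowS = c(-1, 2))
  ## each df/f sample carries the frame noise plus the shared reference-frame
  ## noise, i.e. ~ sqrt(2) * 5% per segment, shrinking with 1/sqrt(n)
  sdAvg <- stats::sd(frames(staN$stack))
  expect_lt(abs(sdAvg / (sqrt(2) * 5 / sqrt(staN$nUsed)) - 1), 0.25)
  expect_error(stimulusTriggeredAverage(mov, 1e4), "in-bounds")
})

test_that("onset latency maps localize threshold crossings", {
  geom <- squareGeometry(3)
  f <- array(0, c(40, 3, 3))
  f[25:40, 1, 1] <- 10                  # steps up at frame 25
  set.seed(2)
  f <- f + array(rnorm(40 * 9, 0, 0.05), c(40, 3, 3))
  f[, 3, 3] <- 0                        # flat, zero-variance pixel
  stack <- movieFrom(f, frameRate = 20, geom = geom, t0 = -1, units = "dff_pct")
  lm <- onsetLatencyMap(stack, interpolate = "none")
  ## frame 25 is 0.2 s after the stimulus (t0 = -1 s at 20 Hz)
  expect_equal(latencies(lm)[1, 1], 0.2)
  expect_true(is.na(latencies(lm)[3, 3]))  # zero-variance pixel masked
  expect_true(is.na(latencies(lm)[2, 2]))  # never crosses
  ## latencies are never negative
  expect_true(all(latencies(lm) >= 0, na.rm = TRUE))
})

test_that("response areas count activated pixels", {
  ## latency-map arithmetic: 400 active pixels at 0.1-mm pitch = 4 mm^2
  geom <- squareGeometry(40)
  L <- matrix(NA_real_, 40, 40)
  L[1:20, 1:20] <- 1.5
  lm <- new("LatencyMap", latencyS = L, geometry = geom)
  expect_equal(responseArea(lm, windowS = c(1, 2)), 4.0)
  ## all-noise stack: area bounded by the Gaussian tail of the threshold
  set.seed(3)
  f <- array(rnorm(100 * 1600), c(100, 40, 40))
  stack <- movieFrom(f, frameRate = 20, geom = geom, t0 = -2, units = "dff_pct")
  ar <- responseArea(stack, windowS = c(1, 2))
  ## P(z > 3.5 SD of a 20-frame estimate) is inflated by SD estimation noise;
  ## even a 20x allowance keeps the false area far below the footprint scale
  expect_lt(ar, 1600 * 0.01 * 20 * stats::pnorm(-3.5) * 100)
  ## area grows monotonically with the true footprint (noiseless discs)
  areas <- vapply(c(2, 6, 12), function(r) {
    fd <- array(0, c(100, 40, 40))
    cx <- 20
    for (i in 1:40) for (j in 1:40)
      if ((i - cx)^2 + (j - cx)^2 <= r^2) fd[60:100, i, j] <- 10
    responseArea(movieFrom(fd, 20, geom, t0 = -2, units = "dff_pct"),
                 windowS = c(1, 2), sdFloorPct = 1)
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("velocity fields recover speed and direction from latency ramps", {
  geom <- squareGeometry(40)
  pc <- pixelCenters(geom)
  ## ramp increasing posteriorly at 1/30 s/mm: posterior propagation, 30 mm/s
  L <- outer(pc$ap, pc$ml, function(a, m) (pc$ap[1] - a) / 30 + 0.2)
  lm <- new("LatencyMap", latencyS = L, geometry = geom)
  vf <- velocityField(lm, smoothPx = 0, fitPx = 4)
  sp <- speeds(vf)[validMask(vf)]
  expect_equal(mean(sp), 30, tolerance = 1e-6)
  mv <- meanVelocityVector(vf)
  expect_equal(unname(mv["speedMmS"]), 30, tolerance = 1e-6)
  expect_equal(abs(unname(mv["directionRad"])), pi, tolerance = 1e-6)
  ## constant map: no pixel carries direction information
  flat <- new("LatencyMap", latencyS = matrix(1, 40, 40), geometry = geom)
  expect_error(velocityField(flat, fitPx = 4), "degenerate")
})

test_that("rotating a latency map rotates directions and keeps speeds", {
  geom <- squareGeometry(40)
  pc <- pixelCenters(geom)
  set.seed(4)
  L <- outer(pc$ap, pc$ml, function(a, m) (pc$ap[1] - a) / 30 + 0.2) +
    matrix(rnorm(1600, 0, 1e-3), 40, 40)
  lm <- new("LatencyMap", latencyS = L, geometry = geom)
  ## rotate the map 90 deg counter-clockwise in the image plane:
  ## new[rowFromLat, col] pattern = transpose + reverse rows
  Lr <- t(L)[rev(seq_len(40)), ]
  lmR <- new("LatencyMap", latencyS = Lr, geometry = geom)
  vf <- velocityField(lm, smoothPx = 0, fitPx = 4)
  vfR <- velocityField(lmR, smoothPx = 0, fitPx = 4)
  mv <- meanVelocityVector(vf); mvR <- meanVelocityVector(vfR)
  expect_equal(unname(mv["speedMmS"]), unname(mvR["speedMmS"]),
               tolerance = 0.02)
  dd <- cortexwaves:::wrapAngle(mvR["directionRad"] - mv["directionRad"])
  expect_equal(abs(unname(dd)), pi / 2, tolerance = 0.02)
})

test_that("activation distributions are normalized and scale-invariant", {
  geom <- squareGeometry(4)
  n <- 400
  sq <- rep(c(0, 1), each = 10, length.out = n)
  f <- array(rep(100 + 20 * sq, 16), c(n, 4, 4))
  mov <- movieFrom(f, frameRate = 20, geom = geom)
  h <- activationDistribution(mov)
  expect_equal(sum(h@mass), 1)
  expect_equal(h@mass[1], 0.5)
  expect_equal(h@mass[20], 0.5)
  ## affine rescaling of the raw intensity leaves the histogram unchanged
  movScaled <- movieFrom(3 * f + 17, frameRate = 20, geom = geom)
  expect_equal(activationDistribution(movScaled)@mass, h@mass)
  expect_error(activationDistribution(movieFrom(array(1, c(n, 4, 4)),
                                                20, geom)), "degenerate")
  expect_error(activationDistribution(mov, minDurationS = 100), "at least")
})

test_that("SWA concentrates activation mass at the lowest bins", {
  geomC <- fieldGeometry(pixelPitchMm = 0.4)
  cfg <- simConfig("SWA", durationS = 40, seed = 31L)
  h <- activationDistribution(renderWidefield(generateSpontaneousEvents(cfg,
                                                                        geomC)))
  expect_equal(which.max(h@mass), 1L)
  expect_gt(sum(h@mass[1:2]), 0.4)
})

test_that("permutation comparison separates SWA from PA histograms", {
  geomC <- fieldGeometry(pixelPitchMm = 0.4)
  mk <- function(state, seed) {
    cfg <- simConfig(state, durationS = 30, seed = seed)
    gt <- if (state == "SWA") generateSpontaneousEvents(cfg, geomC)
          else emptyGroundTruth(cfg, geomC)
    activationDistribution(renderWidefield(gt), id = paste0(state, seed))
  }
  hS <- lapply(1:9, function(i) mk("SWA", 300 + i))
  hP <- lapply(1:9, function(i) mk("PA", 400 + i))
  cmp <- compareDistributionsPermutation(hS, hP, nPerm = 1000, seed = 1)
  expect_true(all(cmp$pAdj >= 1 / 1001))           # permutation p floor
  expect_gt(sum(cmp$pAdj < 0.05), 0)               # separated somewhere
  ## identical groups: adjusted p = 1 everywhere
  same <- compareDistributionsPermutation(hS, hS, nPerm = 200, seed = 2)
  expect_true(all(same$pAdj == 1))
  expect_error(compareDistributionsPermutation(hS[1], hP, 100), "2 animals")
})
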