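test_that("df/f normalization divides by the baseline mean", {
  tr <- rawTrace(rep(2, 4000))
  expect_equal(samples(normalizeDff(tr, c(0, 1))), rep(0, 4000))
  tr2 <- rawTrace(c(rep(2, 2000), rep(2.2, 2000)))
  d <- normalizeDff(tr2, c(0, 1))
  expect_equal(samples(d)[3000], 0.10)
  expect_equal(d@units, "dff")
  ## scale invariance: c * raw gives the same df/f
  tr3 <- rawTrace(100 * (1 + 0.3 * sin(seq(0, 20, length.out = 8000))))
  expect_equal(samples(normalizeDff(tr3, c(0, 1))),
               samples(normalizeDff(rawTrace(7 * samples(tr3)), c(0, 1))))
  expect_error(normalizeDff(rawTrace(rep(-1, 4000)), c(0, 1)), "baseline")
  expect_error(normalizeDff(tr, c(0, 0.2)), "at least")
  expect_error(normalizeDff(tr, c(10, 11)), "within the trace")
})

test_that("the Gaussian low-pass has its -3 dB point at the cutoff", {
  fs <- 2000
  t <- (0:(8 * fs - 1)) / fs
  att <- function(f) {
    tr <- dffTrace(sin(2 * pi * f * t), fs)
    y <- samples(lowpassGaussian(tr, 20))
    mid <- (2 * fs):(6 * fs)
    sqrt(mean(y[mid]^2)) / sqrt(mean(sin(2 * pi * f * t[mid])^2))
  }
  expect_equal(samples(lowpassGaussian(dffTrace(rep(1, 4000), fs))),
               rep(1, 4000))                         # DC preserved
  expect_gt(att(1), 0.98)                            # < 2% attenuation at 1 Hz
  expect_lt(att(100), 0.10)                          # > 90% at 100 Hz
  expect_lt(abs(att(20) - 1 / sqrt(2)), 0.02)        # -3 dB at the cutoff
  expect_error(lowpassGaussian(dffTrace(rnorm(100), 100), cutoffHz = 60),
               "Nyquist")
})

test_that("event detection recovers ground truth on generator traces", {
  expect_equal(nEvents(detectEvents(dffTrace(rep(0, 8000)))), 0L)
  ## noiseless: exact count, onsets within one kernel rise time
  cfgN <- simConfig("SWA", durationS = 300, seed = 21L, noiseSd = 0)
  gtN <- generateSpontaneousEvents(cfgN)
  trN <- renderPhotometry(gtN)$S1
  evN <- detectEvents(lowpassGaussian(normalizeDff(trN, pickBaselineWindow(trN))))
  expect_equal(nEvents(evN), length(siteOnsets(gtN)$S1))
  expect_lt(max(abs(onsets(evN) - siteOnsets(gtN)$S1)), cfgN@tauRiseS)
  ## default noise: recall and precision >= 0.95
  cfg <- simConfig("SWA", durationS = 600, seed = 22L)
  gt <- generateSpontaneousEvents(cfg)
  ev <- detectPipeline(renderPhotometry(gt)$S1)
  m <- interregionDelays(truthEventList(siteOnsets(gt)$S1), ev,
                         matchWindowS = 0.5)
  expect_gte(m$nMatched / length(siteOnsets(gt)$S1), 0.95)  # recall
  expect_gte(m$nMatched / nEvents(ev), 0.95)                # precision
  ## event lists are structurally valid
  e <- events(ev)
  expect_true(all(diff(e$onsetS) > 0))
  expect_true(all(e$peakS >= e$onsetS))
  expect_true(all(e$durationS > 0))
})

test_that("event detection is translation-equivariant", {
  cfg <- simConfig("SWA", durationS = 120, seed = 23L)
  gt <- generateSpontaneousEvents(cfg)
  tr <- renderPhotometry(gt)$S1
  d <- lowpassGaussian(normalizeDff(tr, pickBaselineWindow(tr)))
  shiftN <- 4000L  # 2 s
  dShift <- dffTrace(c(samples(d)[(shiftN + 1):length(samples(d))]),
                     fsHz(d), site = site(d))
  a <- onsets(detectEvents(d))
  b <- onsets(detectEvents(dShift))
  a <- a[a > 2 & a < max(a) - 2] - 2
  matched <- vapply(a, function(o) min(abs(b - o)), numeric(1))
  expect_lt(stats::median(matched), 2e-3)
})

test_that("response latencies follow the contract", {
  ev <- truthEventList(c(5.098, 12.0))
  r <- responseLatency(ev, c(5.0, 8.0, 20.0), mode = "swa_onset",
                       traceEndS = 30)
  expect_equal(r$latencyS[1], 0.098)          # 98-ms onset latency
  expect_equal(r$latencyS[2], 4.0)            # next onset within 5 s
  expect_true(is.na(r$latencyS[3]))           # nothing within reach
  expect_equal(r$flag[3], "missing")
  ## pa_peak: maximum within the 2-s window
  fs <- 1000
  x <- numeric(6 * fs)
  x[round(2.3 * fs) + 1L] <- 1                 # peak 0.3 s after stimulus at 2
  rp <- responseLatency(dffTrace(x, fs), 2.0, mode = "pa_peak")
  expect_equal(rp$latencyS, 0.3, tolerance = 1e-6)
  rt <- responseLatency(dffTrace(x, fs), 5.5, mode = "pa_peak")
  expect_equal(rt$flag, "truncated")
})

test_that("shuffled onsets stay within the jitter range and break locking", {
  st <- generateStimulusTrain("visual", 50, isiS = 10)
  sh <- shuffleOnsets(st, jitterRangeS = 2, seed = 1)
  expect_length(sh, 50L)
  expect_true(all(abs(sort(onsets(st)) - sort(onsets(sh))) <= 1 + 1e-12))
  expect_true(!is.unsorted(onsets(sh)))
  ## stimulus-locked mean response (real) > (shuffled) on generator data
  cfg <- simConfig("SWA", durationS = 420, seed = 24L)
  gt <- generateSpontaneousEvents(cfg)
  stg <- generateStimulusTrain("somatosensory", 40, isiS = 10, tStart = 6)
  gt <- applyStimulusGating(stg, gt)
  tr <- renderPhotometry(gt)$S1
  d <- samples(lowpassGaussian(normalizeDff(tr, pickBaselineWindow(tr))))
  locked <- function(onsetsS) {
    mean(vapply(onsetsS, function(s) {
      i <- floor(s * 2000) + 1L
      mean(d[i:(i + 1000L)])
    }, numeric(1)))
  }
  shg <- shuffleOnsets(stg, 2, seed = 2)
  expect_gt(locked(onsets(stg)), locked(onsets(shg)))
})

test_that("cross-correlation sign convention: positive lag = A leads", {
  fs <- 1000
  set.seed(1)
  a <- as.numeric(stats::filter(rnorm(20 * fs), rep(1 / 50, 50), sides = 2))
  a[is.na(a)] <- 0
  shift <- round(0.15 * fs)
  b <- c(rep(0, shift), a[1:(length(a) - shift)])
  ta <- dffTrace(a, fs); tb <- dffTrace(b, fs)
  cc <- crossCorrelogram(ta, tb, maxLagS = 1)
  expect_equal(cc$peakLagS, 0.15, tolerance = 0.02)
  same <- crossCorrelogram(ta, ta, maxLagS = 1)
  expect_equal(same$peakLagS, 0)
  expect_equal(same$peakValue, 1, tolerance = 1e-6)
  expect_error(crossCorrelogram(dffTrace(rep(1, 5000), fs), ta, 1),
               "zero-variance")
  ## S1 leads V1 on generator SWA data
  cfg <- simConfig("SWA", durationS = 240, seed = 25L)
  tr <- renderPhotometry(generateSpontaneousEvents(cfg))
  ccg <- crossCorrelogram(tr$S1, tr$V1, maxLagS = 1)
  expect_gt(ccg$peakLagS, 0)
})

test_that("inter-regional delays and lead fractions are recovered", {
  a <- truthEventList(c(5, 15, 25))
  expect_equal(interregionDelays(a, a)$delaysS, c(0, 0, 0))
  b <- truthEventList(c(5.1, 15.1, 25.1), "V1")
  r <- interregionDelays(a, b)
  expect_equal(r$delaysS, rep(0.1, 3))
  expect_equal(r$leaderFractionA, 1)
  expect_error(interregionDelays(a, truthEventList(numeric())), "non-empty")
  expect_equal(interregionDelays(a, truthEventList(c(100, 200)))$nMatched, 0L)
  ## noiseless generator: recovered delays match geometry within 2 samples
  cfg <- simConfig("SWA", durationS = 300, seed = 26L, noiseSd = 0)
  gt <- generateSpontaneousEvents(cfg)
  tr <- renderPhotometry(gt)
  evS <- detectPipeline(tr$S1); evV <- detectPipeline(tr$V1)
  det <- interregionDelays(evS, evV)
  tru <- interregionDelays(truthEventList(siteOnsets(gt)$S1),
                           truthEventList(siteOnsets(gt)$V1, "V1"))
  expect_equal(det$nMatched, tru$nMatched)
  expect_lt(abs(mean(det$delaysS) - mean(tru$delaysS)), 2 / 2000)
})
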