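test_that("stimulus trains have the requested structure", {
  st <- generateStimulusTrain("somatosensory", nStimuli = 3, isiS = 10)
  expect_equal(onsets(st), c(0, 10, 20))
  ## block paradigm: 4 s at 3 Hz = 12 pulses per block
  blk <- generateStimulusTrain("somatosensory", nStimuli = 1, isiS = 20,
                               trainSpec = list(rateHz = 3, durationS = 4))
  expect_length(blk, 12L)
  expect_equal(max(onsets(blk)), 11 / 3)
  two <- generateStimulusTrain("visual", nStimuli = 2, isiS = 20,
                               trainSpec = list(rateHz = 3, durationS = 4))
  expect_length(two, 24L)
  ## jittered trains are reproducible under a fixed seed
  a <- generateStimulusTrain("visual", 100, isiS = c(2, 4), seed = 7)
  b <- generateStimulusTrain("visual", 100, isiS = c(2, 4), seed = 7)
  expect_identical(onsets(a), onsets(b))
  expect_error(generateStimulusTrain("visual", 3, isiS = -1), "positive")
  expect_error(generateStimulusTrain("visual", 3, isiS = 10,
                                     trainSpec = list(rateHz = 0, durationS = 4)),
               "positive")
})

test_that("spontaneous waves respect the hard refractory period", {
  cfg <- simConfig("SWA", durationS = 600, seed = 1L)
  gt <- generateSpontaneousEvents(cfg)
  expect_gt(nEvents(gt), 50)
  expect_true(all(diff(events(gt)$time) >= cfg@refractoryS))
  for (s in c("S1", "V1"))
    expect_true(all(diff(siteOnsets(gt)[[s]]) >= cfg@refractoryS - 0.2))
})

test_that("anterior-only origins force S1 to lead V1 everywhere", {
  cfg <- simConfig("SWA", durationS = 300, seed = 2L, anteriorOriginProb = 1,
                   directionJitterSd = 0)
  gt <- generateSpontaneousEvents(cfg)
  expect_true(all(siteOnsets(gt)$S1 < siteOnsets(gt)$V1))
})

test_that("per-site onsets follow the plane-wave geometry exactly", {
  cfg <- simConfig("SWA", durationS = 400, seed = 3L)
  gt <- generateSpontaneousEvents(cfg)
  ev <- events(gt)
  geom <- geometry(gt)
  s1 <- siteCoords(geom, "S1"); v1 <- siteCoords(geom, "V1")
  dS1 <- cortexwaves:::travelTimeS(s1["ap"], s1["ml"], ev$originAp,
                                   ev$originMl, ev$directionRad, ev$speedMmS)
  dV1 <- cortexwaves:::travelTimeS(v1["ap"], v1["ml"], ev$originAp,
                                   ev$originMl, ev$directionRad, ev$speedMmS)
  expect_equal(sort(ev$time + dS1), siteOnsets(gt)$S1, tolerance = 1e-12)
  expect_equal(sort(ev$time + dV1), siteOnsets(gt)$V1, tolerance = 1e-12)
})

test_that("a too-short recording yields an empty, flagged ground truth", {
  cfg <- simConfig("SWA", durationS = 0.5, seed = 4L)
  expect_warning(gt <- generateSpontaneousEvents(cfg), "too short")
  expect_true(gt@empty)
  expect_equal(nEvents(gt), 0L)
})

test_that("ground-truth statistics match the configured rates", {
  ## S1-leading fraction ~ anterior-origin probability (0.6), speed ~ 30.5
  leads <- 0; total <- 0; speeds <- numeric()
  for (seed in 1:6) {
    gt <- generateSpontaneousEvents(simConfig("SWA", durationS = 600,
                                              seed = seed))
    m <- interregionDelays(truthEventList(siteOnsets(gt)$S1, "S1"),
                           truthEventList(siteOnsets(gt)$V1, "V1"))
    leads <- leads + sum(m$delaysS > 0)
    total <- total + m$nMatched
    speeds <- c(speeds, events(gt)$speedMmS)
  }
  se <- sqrt(0.6 * 0.4 / total)
  expect_lt(abs(leads / total - 0.6), 3 * se)
  expect_lt(abs(mean(speeds) - 30.5), 3 * 5.3 / sqrt(length(speeds)))
  expect_true(all(speeds > 0))
})

test_that("stimulus gating obeys the refractory gate", {
  cfg <- simConfig("SWA", durationS = 400, seed = 5L, pEvoke = 1)
  gt <- generateSpontaneousEvents(cfg)
  st <- generateStimulusTrain("somatosensory", 35, isiS = 10, tStart = 8)
  gt <- applyStimulusGating(st, gt)
  tab <- stimulusTable(gt)
  ## pEvoke = 1: every out-of-refractory stimulus succeeds
  expect_true(all(tab$success[!tab$inRefractory]))
  ## evoked events all trace back to a stimulus
  ev <- events(gt)
  expect_true(all(!is.na(ev$stimIndex[ev$evoked])))
  expect_true(all(is.na(ev$stimIndex[!ev$evoked])))
  ## successful out-of-refractory latencies sit near the configured 98 ms
  latOk <- tab$latencyMs[tab$success & !tab$inRefractory]
  expect_lt(abs(mean(latOk) - 98), 10)
  ## refractory consistency survives gating
  expect_true(all(diff(ev$time) >= cfg@refractoryS - 1e-9 | ev$evoked[-1]))
})

test_that("pRefractory = 0 forces failure shortly after a wave", {
  cfg <- simConfig("SWA", durationS = 60, seed = 6L, pRefractory = 0)
  gt <- wavesGroundTruth(singleWave(t = 10, ap = -0.2, ml = 2.5, dir = pi), cfg)
  st <- generateStimulusTrain("somatosensory", 1, isiS = 10, tStart = 10.5)
  gt <- applyStimulusGating(st, gt)
  tab <- stimulusTable(gt)
  expect_true(tab$inRefractory[1])
  expect_false(tab$success[1])
})

test_that("gate-open success rate matches pEvoke within Monte-Carlo error", {
  succ <- 0; tot <- 0
  for (seed in 11:14) {
    cfg <- simConfig("SWA", durationS = 1300, seed = seed)
    gt <- generateSpontaneousEvents(cfg)
    st <- generateStimulusTrain("somatosensory", 125, isiS = 10, tStart = 8)
    tab <- stimulusTable(applyStimulusGating(st, gt))
    succ <- succ + sum(tab$success[!tab$inRefractory])
    tot <- tot + sum(!tab$inRefractory)
  }
  expect_lt(abs(succ / tot - 0.90), 3 * sqrt(0.9 * 0.1 / tot))
})

test_that("photometry rendering is deterministic and kernel-accurate", {
  cfg <- simConfig("SWA", durationS = 20, seed = 7L, noiseSd = 0)
  gt <- wavesGroundTruth(singleWave(t = 5, ap = -0.2, ml = 2.5, dir = pi), cfg)
  tr <- renderPhotometry(gt)
  ## peak time = onset + kernel argmax
  tPk <- cfg@tauRiseS * log(1 + cfg@tauDecayS / cfg@tauRiseS)
  s1On <- siteOnsets(gt)$S1[1]
  pk <- (which.max(samples(tr$S1)) - 1) / fsHz(tr$S1)
  expect_lt(abs(pk - (s1On + tPk)), 2 / fsHz(tr$S1))
  ## V1 peak is delayed by the travel time
  pkV <- (which.max(samples(tr$V1)) - 1) / fsHz(tr$V1)
  expect_lt(abs((pkV - pk) - (siteOnsets(gt)$V1[1] - s1On)), 2e-3)
  ## bit-identical rerun under the same config/seed
  cfgN <- simConfig("SWA", durationS = 20, seed = 8L)
  gtN <- generateSpontaneousEvents(cfgN)
  expect_identical(samples(renderPhotometry(gtN)$S1),
                   samples(renderPhotometry(gtN)$S1))
})

test_that("SWA traces are dominated by near-baseline silent periods", {
  cfg <- simConfig("SWA", durationS = 600, seed = 9L, noiseSd = 0)
  gt <- generateSpontaneousEvents(cfg)
  x <- samples(renderPhotometry(gt)$S1) / 100 - 1  # noiseless activity
  ## at 10 waves/min the kernel exceeds 5% of the event amplitude for about
  ## 3 s out of a 6-s mean interval, so near-baseline samples are ~half
  expect_gt(mean(abs(x) < 0.05 * cfg@amplitude), 0.45)
})

test_that("widefield rendering matches the plane-wave timing and footprints", {
  ## noiseless wavefront: activation 3 mm apart along the AP axis = 100 ms
  cfg <- simConfig("SWA", durationS = 8, seed = 10L, noiseSd = 0)
  gt <- wavesGroundTruth(singleWave(t = 3, speed = 30, dir = 0), cfg)
  sta <- stimulusTriggeredAverage(renderWidefield(gt), 3, windowS = c(-1, 2.5))
  lm <- onsetLatencyMap(sta$stack, sdFloorPct = 5)
  L <- latencies(lm)
  ## rows 30 px (3 mm) apart, same column, anterior of the origin
  expect_equal(L[13, 30] - L[43, 30], 0.1, tolerance = 0.01)
  ## PA evoked disc: pixel count forced by area / pitch^2
  cfgPa <- simConfig("PA", durationS = 6, seed = 11L, noiseSd = 0)
  st <- generateStimulusTrain("visual", 1, isiS = 10, tStart = 3)
  movPa <- renderWidefield(emptyGroundTruth(cfgPa, stimuli = st))
  d <- frames(dffMovie(movPa, 3.0))
  iPk <- 64  # ~0.15 s after the stimulus
  expect_equal(sum(d[iPk, , ] > 1e-6), round(6.9 / 0.01))
  ## geometry too coarse for the field
  bad <- fieldGeometry(apLim = c(0.05, -0.05), mlLim = c(2, 2.1),
                       pixelPitchMm = 0.2, sites = matrix(numeric(0), 0, 2,
                         dimnames = list(NULL, c("ap", "ml"))))
  cfgBad <- simConfig("SWA", durationS = 5, seed = 1L)
  expect_error(renderWidefield(wavesGroundTruth(singleWave(), cfgBad,
                                                geometry = bad), bad),
               "pitch")
})

test_that("SWA LFP gates broadband power on events and PA peaks near 15 Hz", {
  cfg <- simConfig("SWA", durationS = 60, seed = 12L)
  gt <- wavesGroundTruth(
    do.call(rbind, lapply(c(10, 20, 30, 40), function(t)
      singleWave(t = t, ap = -3.8, ml = 2.0, dir = 0))), cfg)
  lfp <- renderLfp(gt, site = "V1")
  x <- samples(lfp); fs <- fsHz(lfp)
  inEvent <- function(t) any(t - c(10, 20, 30, 40) > 0 &
                             t - c(10, 20, 30, 40) < 1)
  tt <- (seq_along(x) - 1) / fs
  ev <- vapply(tt, inEvent, logical(1))
  silent <- !vapply(tt, function(t) inEvent(t) ||
                      any(t - c(10, 20, 30, 40) > -0.1 &
                          t - c(10, 20, 30, 40) < 1.6), logical(1))
  expect_lt(sqrt(mean(x[silent]^2)), 0.1 * sqrt(mean(x[ev]^2)))
  ## PA spectrogram peaks within 15 +/- 2 Hz
  cfgPa <- simConfig("PA", durationS = 60, seed = 13L)
  lfpPa <- renderLfp(emptyGroundTruth(cfgPa), site = "V1")
  sg <- multitaperSpectrogram(lfpPa, windowS = 2, stepS = 1, tw = 2, k = 3,
                              fpass = c(1, 40))
  pkHz <- sg@freqHz[which.max(colMeans(sg@power))]
  expect_lt(abs(pkHz - 15), 2)
})

test_that("stimulus gamma packets raise post-stimulus gamma power", {
  cfg <- simConfig("SWA", durationS = 120, seed = 14L)
  gt <- generateSpontaneousEvents(cfg)
  st <- generateStimulusTrain("visual", 10, isiS = 10, tStart = 6)
  gt <- applyStimulusGating(st, gt)
  lfp <- renderLfp(gt, site = "V1")
  r <- logFoldChange(lfp, stimuli = st, band = c(35, 200),
                     postWindow = c(0, 0.1))
  expect_gt(r$logFC, 0.5)
})
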