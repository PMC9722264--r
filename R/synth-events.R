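## draw propagation speeds from Normal(mean, sd) truncated to > 0
drawSpeeds <- function(n, meanMmS, sdMmS) {
  out <- stats::rnorm(n, meanMmS, sdMmS)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), meanMmS, sdMmS)
    bad <- bad[out[bad] <= 0]
  }
  out
}

## per-site wave onsets implied by the plane-wave model
computeSiteOnsets <- function(events, geometry) {
  out <- list()
  for (s in rownames(geometry@sites)) {
    sc <- siteCoords(geometry, s)
    if (nrow(events)) {
      t <- events$time + travelTimeS(sc["ap"], sc["ml"], events$originAp,
                                     events$originMl, events$directionRad,
                                     events$speedMmS)
      out[[s]] <- sort(as.numeric(t))
    } else out[[s]] <- numeric()
  }
  out
}

## one new wave event row
newEventRow <- function(time, originAp, originMl, speed, direction,
                        evoked = FALSE, stimIndex = NA_integer_) {
  data.frame(time = time, originAp = originAp, originMl = originMl,
             speedMmS = speed, directionRad = direction, evoked = evoked,
             stimIndex = stimIndex)
}

#' Generate spontaneous slow-wave events
#'
#' Spontaneous waves form a renewal process with a hard refractory period:
#' inter-event intervals are `refractoryS` plus an exponential with mean
#' chosen so that the average rate matches `waveRatePerMin`. Each wave is
#' assigned an origin (anterior band around the S1 AP coordinate with
#' probability `anteriorOriginProb`, otherwise the posterior band around the
#' V1 AP coordinate, with uniform ML jitter), a truncated-normal propagation
#' speed, and a direction pointing away from its origin band along the AP
#' axis with Gaussian angular jitter. Per-site onsets follow the plane-wave
#' model: onset = wave time + (projection of site onto the propagation
#' direction - projection of the origin) / speed.
#'
#' @param config a [SimConfig-class] with `state == "SWA"`.
#' @param geometry a [FieldGeometry-class].
#' @return A [GroundTruth-class]. When the duration is too short for a single
#'   event the ground truth is empty and flagged (with a warning).
#' @examples
#' gt <- generateSpontaneousEvents(simConfig("SWA", durationS = 120, seed = 1L))
#' nEvents(gt)
#' @export
generateSpontaneousEvents <- function(config, geometry = fieldGeometry()) {
  if (config@state != "SWA")
    stop("spontaneous slow-wave generation requires state = 'SWA'")
  withStageSeed(config, "events")
  meanIntS <- 60 / config@waveRatePerMin
  if (meanIntS <= config@refractoryS)
    stop("wave rate incompatible with the refractory period")
  expMean <- meanIntS - config@refractoryS
  nMax <- ceiling(config@durationS / meanIntS * 2) + 20L
  gaps <- config@refractoryS + stats::rexp(nMax, rate = 1 / expMean)
  times <- cumsum(gaps)
  times <- times[times < config@durationS]
  if (!length(times)) {
    warning("duration too short for a single spontaneous event")
    return(new("GroundTruth",
               events = data.frame(time = numeric(), originAp = numeric(),
                                   originMl = numeric(), speedMmS = numeric(),
                                   directionRad = numeric(), evoked = logical(),
                                   stimIndex = integer()),
               siteOnsets = computeSiteOnsets(data.frame(), geometry),
               stimuli = data.frame(), nMerged = 0L, geometry = geometry,
               config = config, empty = TRUE))
  }
  n <- length(times)
  anterior <- stats::runif(n) < config@anteriorOriginProb
  apBand <- ifelse(anterior, siteCoords(geometry, "S1")["ap"],
                   siteCoords(geometry, "V1")["ap"])
  originAp <- apBand + stats::runif(n, -config@apOriginJitter, config@apOriginJitter)
  originMl <- stats::runif(n, config@mlOriginRange[1], config@mlOriginRange[2])
  ## anterior origins propagate posteriorly (theta = pi), posterior anteriorly
  direction <- wrapAngle(ifelse(anterior, pi, 0) +
                         stats::rnorm(n, 0, config@directionJitterSd))
  speed <- drawSpeeds(n, config@speedMeanMmS, config@speedSdMmS)
  events <- newEventRow(times, originAp, originMl, speed, direction)
  new("GroundTruth", events = events,
      siteOnsets = computeSiteOnsets(events, geometry),
      stimuli = data.frame(), nMerged = 0L,
      geometry = geometry, config = config, empty = FALSE)
}

#' Gate stimuli on the slow-wave refractory period and insert evoked waves
#'
#' Walks the stimuli in time order. For each stimulus the time since the most
#' recent wave (spontaneous or previously evoked) is computed; when it is at
#' least `refractoryS` an evoked wave is inserted with probability `pEvoke`
#' at the modality's primary site (forepaw -> S1, visual -> V1) after a
#' latency drawn from the configured Normal distribution. Inside the
#' refractory window the success probability drops to `pRefractory` and a
#' successful response initiates only once the network recovers (last wave +
#' `refractoryS`) plus the same latency, reproducing the long, variable
#' response times of refractory stimuli. Spontaneous events falling within
#' `refractoryS` after an inserted evoked wave are absorbed (merged) by it
#' and counted in `nMerged`.
#'
#' @param stimuli a [StimulusTrain-class].
#' @param groundTruth a [GroundTruth-class] with spontaneous events.
#' @param config a [SimConfig-class]; defaults to the ground truth's config.
#' @return The augmented [GroundTruth-class]: evoked events appended, per-site
#'   onsets recomputed, and the stimulus table filled (see
#'   [GroundTruth-class]).
#' @examples
#' cfg <- simConfig("SWA", durationS = 300, seed = 2L)
#' gt <- generateSpontaneousEvents(cfg)
#' st <- generateStimulusTrain("somatosensory", nStimuli = 25, isiS = 10,
#'                             tStart = 5)
#' gt <- applyStimulusGating(st, gt)
#' head(stimulusTable(gt))
#' @export
applyStimulusGating <- function(stimuli, groundTruth, config = groundTruth@config) {
  stopifnot(is(stimuli, "StimulusTrain"), is(groundTruth, "GroundTruth"))
  withStageSeed(config, "gating")
  lat <- primaryLatency(config, modality(stimuli))
  origin <- siteCoords(groundTruth@geometry, lat$site)
  ## evoked waves propagate away from the primary site along the AP axis
  baseDir <- if (lat$site == "S1") pi else 0
  spont <- groundTruth@events
  spontTimes <- spont$time
  evokedRows <- list()
  mergedSpont <- logical(nrow(spont))
  stimOn <- onsets(stimuli)
  n <- length(stimOn)
  tab <- data.frame(onsetS = stimOn, modality = modality(stimuli),
                    timeSinceWaveS = NA_real_, timeSinceSpontS = NA_real_,
                    inRefractory = FALSE, success = FALSE,
                    waveTimeS = NA_real_, latencyMs = NA_real_)
  evokedTimes <- numeric()
  for (i in seq_len(n)) {
    s <- stimOn[i]
    liveSpont <- spontTimes[!mergedSpont & spontTimes < s]
    lastSpont <- if (length(liveSpont)) max(liveSpont) else -Inf
    lastEvoked <- if (length(evokedTimes)) max(evokedTimes[evokedTimes < s]) else -Inf
    lastWave <- max(lastSpont, lastEvoked)
    tsl <- s - lastWave
    tab$timeSinceWaveS[i] <- tsl
    tab$timeSinceSpontS[i] <- s - lastSpont
    inRef <- is.finite(tsl) && tsl < config@refractoryS
    tab$inRefractory[i] <- inRef
    p <- if (inRef) config@pRefractory else config@pEvoke
    if (stats::runif(1) < p) {
      latMs <- stats::rnorm(1, lat$meanMs, lat$sdMs)
      latMs <- max(latMs, 1)
      waveTime <- if (inRef) lastWave + config@refractoryS + latMs / 1000
                  else s + latMs / 1000
      tab$success[i] <- TRUE
      tab$waveTimeS[i] <- waveTime
      tab$latencyMs[i] <- 1000 * (waveTime - s)
      dir <- wrapAngle(baseDir + stats::rnorm(1, 0, config@directionJitterSd))
      speed <- drawSpeeds(1, config@speedMeanMmS, config@speedSdMmS)
      evokedRows[[length(evokedRows) + 1L]] <-
        newEventRow(waveTime, origin["ap"], origin["ml"], speed, dir,
                    evoked = TRUE, stimIndex = i)
      evokedTimes <- c(evokedTimes, waveTime)
      ## merge spontaneous events overlapping the evoked wave's refractory span
      absorb <- !mergedSpont & spontTimes > waveTime &
        spontTimes < waveTime + config@refractoryS
      mergedSpont[absorb] <- TRUE
    }
  }
  keptSpont <- spont[!mergedSpont, , drop = FALSE]
  allEvents <- rbind(keptSpont, do.call(rbind, evokedRows))
  if (is.null(allEvents)) allEvents <- keptSpont
  allEvents <- allEvents[order(allEvents$time), , drop = FALSE]
  rownames(allEvents) <- NULL
  new("GroundTruth", events = allEvents,
      siteOnsets = computeSiteOnsets(allEvents, groundTruth@geometry),
      stimuli = tab, nMerged = as.integer(sum(mergedSpont)),
      geometry = groundTruth@geometry, config = config,
      empty = nrow(allEvents) == 0L)
}
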