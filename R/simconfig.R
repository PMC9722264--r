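#' Reference evoked-latency table
#'
#' Per-stimulus wave-onset latency distributions by modality and site, in ms.
#' The generator draws the primary-site latency (forepaw -> S1, visual -> V1)
#' from Normal(meanMs, sdMs); distant-site rows are reference values that the
#' propagation model reproduces approximately (distant onset = primary onset +
#' inter-site path length / wave speed) and are kept for documentation and
#' validation.
#'
#' @return data.frame(modality, site, laterality, meanMs, sdMs, primary).
#' @export
defaultEvokedLatencies <- function() {
  data.frame(
    modality   = c("somatosensory", "somatosensory", "somatosensory",
                   "visual", "visual", "visual"),
    site       = c("S1", "V1", "V1", "V1", "S1", "S1"),
    laterality = c("contra", "ipsi", "contra", "contra", "ipsi", "contra"),
    meanMs     = c(98, 204, 228, 115, 263, 288),
    sdMs       = c(7, 7, 8, 4, 10, 11),
    primary    = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Reference evoked-area table
#'
#' Evoked response footprint (mm^2) by state and modality.
#'
#' @return data.frame(state, modality, areaMm2).
#' @export
defaultEvokedAreas <- function() {
  data.frame(
    state    = c("SWA", "SWA", "PA", "PA"),
    modality = c("visual", "somatosensory", "visual", "somatosensory"),
    areaMm2  = c(22.8, 23.1, 6.9, 7.5),
    stringsAsFactors = FALSE)
}

#' Construct a generator configuration
#'
#' Defaults are the study conditions: slow waves around 0.1 Hz (10 waves/min)
#' with a hard 2.0-s refractory period, anterior origins in 60% of waves,
#' propagation speed Normal(30.5, 5.3) mm/s truncated positive, 90%
#' evoked-wave probability outside the refractory window (20% inside),
#' site-specific evoked latencies (98 ms forepaw -> S1, 115 ms visual -> V1),
#' calcium kernel with 50-ms rise and 1-s decay, PA fluctuations centred on
#' 15 Hz, and additive Gaussian noise with SD 0.1 of the event amplitude.
#'
#' @param state "SWA" or "PA".
#' @param durationS recording duration in seconds.
#' @param seed integer RNG seed (NA = leave the RNG state alone).
#' @param fsTraceHz,frameRateHz sampling rates for traces and movies.
#' @param waveRatePerMin,refractoryS,anteriorOriginProb,speedMeanMmS,speedSdMmS
#'   spontaneous wave statistics.
#' @param pEvoke,pRefractory evoked-wave probabilities outside/inside the
#'   refractory window.
#' @param evokedLatencyMs,evokedAreaMm2 see [defaultEvokedLatencies()],
#'   [defaultEvokedAreas()].
#' @param tauRiseS,tauDecayS calcium kernel time constants (s).
#' @param paBandHz centre frequency of PA-state fluctuations (Hz).
#' @param noiseSd noise SD as a fraction of the event amplitude.
#' @param amplitude event amplitude in df/f units.
#' @param directionJitterSd SD (rad) of the wave direction about the AP axis.
#' @param mlOriginRange uniform ML range (mm) for spontaneous wave origins.
#' @param apOriginJitter half-range (mm) of AP jitter around the origin bands.
#' @param eventDurationS nominal up-state duration for the LFP renderer (s).
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig("SWA", durationS = 120, seed = 1L)
#' cfg
#' @export
simConfig <- function(state = c("SWA", "PA"), durationS = 600,
                      seed = NA_integer_,
                      fsTraceHz = 2000, frameRateHz = 20,
                      waveRatePerMin = 10, refractoryS = 2.0,
                      anteriorOriginProb = 0.6,
                      speedMeanMmS = 30.5, speedSdMmS = 5.3,
                      pEvoke = 0.90, pRefractory = 0.20,
                      evokedLatencyMs = defaultEvokedLatencies(),
                      evokedAreaMm2 = defaultEvokedAreas(),
                      tauRiseS = 0.05, tauDecayS = 1.0,
                      paBandHz = 15, noiseSd = 0.1, amplitude = 1,
                      directionJitterSd = 0.15,
                      mlOriginRange = c(1.5, 3.0), apOriginJitter = 0.2,
                      eventDurationS = 1.0) {
  state <- match.arg(state)
  new("SimConfig", state = state, durationS = durationS,
      fsTraceHz = fsTraceHz, frameRateHz = frameRateHz,
      waveRatePerMin = waveRatePerMin, refractoryS = refractoryS,
      anteriorOriginProb = anteriorOriginProb, speedMeanMmS = speedMeanMmS,
      speedSdMmS = speedSdMmS, pEvoke = pEvoke, pRefractory = pRefractory,
      evokedLatencyMs = evokedLatencyMs, evokedAreaMm2 = evokedAreaMm2,
      tauRiseS = tauRiseS, tauDecayS = tauDecayS, paBandHz = paBandHz,
      noiseSd = noiseSd, amplitude = amplitude,
      directionJitterSd = directionJitterSd,
      mlOriginRange = as.numeric(mlOriginRange),
      apOriginJitter = apOriginJitter, eventDurationS = eventDurationS,
      seed = as.integer(seed))
}

## look up the primary-site latency distribution for a modality
primaryLatency <- function(config, modality) {
  tab <- config@evokedLatencyMs
  row <- tab[tab$modality == modality & tab$primary, , drop = FALSE]
  if (!nrow(row)) stop("no primary latency entry for modality ", modality)
  list(site = row$site[1], meanMs = row$meanMs[1], sdMs = row$sdMs[1])
}

## look up the evoked footprint area for (state, modality)
evokedArea <- function(config, modality) {
  tab <- config@evokedAreaMm2
  row <- tab[tab$state == config@state & tab$modality == modality, , drop = FALSE]
  if (!nrow(row)) stop("no evoked area entry for ", config@state, "/", modality)
  row$areaMm2[1]
}

## seed the RNG reproducibly for a named stage; no-op when seed is NA
withStageSeed <- function(config, stage) {
  if (!is.na(config@seed)) {
    offset <- sum(utf8ToInt(stage)) %% 1000L
    set.seed((config@seed * 1009L + offset) %% .Machine$integer.max)
  }
  invisible(NULL)
}
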