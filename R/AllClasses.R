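#' @import methods
NULL

## Central S4 classes. Constructors with documented defaults live in the
## module files (geometry.R, simconfig.R, ...); validity here enforces the
## structural invariants.

#' FieldGeometry: cortical field-of-view geometry
#'
#' Describes the imaged cortical field in stereotaxic millimetres.
#' Anterior-posterior (AP) coordinates follow the stereotaxic convention
#' (bregma = 0, more negative = more posterior); image rows run
#' anterior to posterior, columns medial to lateral. Direction angles used
#' throughout the package are 0 = anterior, +pi/2 = lateral, in radians.
#'
#' @slot apLim numeric(2), AP coordinate of the anterior and posterior field
#'   edges (apLim[1] > apLim[2]).
#' @slot mlLim numeric(2), ML coordinate of the medial and lateral edges.
#' @slot pixelPitchMm numeric(1), pixel size in mm.
#' @slot sites matrix with columns `ap`, `ml` and one row per recording site
#'   (rows named, e.g. "S1", "V1").
#' @seealso [fieldGeometry()]
#' @export
setClass("FieldGeometry",
  representation(apLim = "numeric", mlLim = "numeric",
                 pixelPitchMm = "numeric", sites = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@pixelPitchMm) != 1L || object@pixelPitchMm <= 0)
      msg <- c(msg, "pixelPitchMm must be a single positive number")
    if (length(object@apLim) != 2L || object@apLim[1] <= object@apLim[2])
      msg <- c(msg, "apLim must be length 2 with apLim[1] (anterior) > apLim[2]")
    if (length(object@mlLim) != 2L || object@mlLim[2] <= object@mlLim[1])
      msg <- c(msg, "mlLim must be length 2 increasing")
    if (!is.null(object@sites) && nrow(object@sites) > 0) {
      if (!all(c("ap", "ml") %in% colnames(object@sites)))
        msg <- c(msg, "sites must have columns 'ap' and 'ml'")
      else {
        inside <- object@sites[, "ap"] <= object@apLim[1] &
          object@sites[, "ap"] >= object@apLim[2] &
          object@sites[, "ml"] >= object@mlLim[1] &
          object@sites[, "ml"] <= object@mlLim[2]
        if (!all(inside))
          msg <- c(msg, "all sites must lie inside the field")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' SimConfig: synthetic-data generator configuration
#'
#' Holds every tunable of the ground-truth generator. Defaults reproduce the
#' study conditions: ~10 slow waves per minute (around 0.1 Hz), a 2.0-s hard
#' refractory period, 60% anterior wave origins, propagation speed
#' 30.5 +/- 5.3 mm/s, 90% evoked-wave probability outside the refractory
#' window, site/modality evoked latencies (98 ms forepaw->S1,
#' 115 ms visual->V1, ...) and evoked response areas (22.8/23.1 mm^2 in SWA,
#' 6.9/7.5 mm^2 in PA for visual/somatosensory).
#'
#' @slot state "SWA" or "PA".
#' @slot durationS recording duration (s).
#' @slot fsTraceHz photometry/LFP sampling rate (Hz), default 2000.
#' @slot frameRateHz movie frame rate (Hz), default 20.
#' @slot waveRatePerMin spontaneous wave rate (1/min), default 10.
#' @slot refractoryS hard refractory period tau_r (s), default 2.
#' @slot anteriorOriginProb probability a spontaneous wave starts anteriorly.
#' @slot speedMeanMmS,speedSdMmS propagation speed distribution (mm/s).
#' @slot pEvoke evoked-wave probability outside the refractory window.
#' @slot pRefractory evoked-wave probability inside the refractory window.
#' @slot evokedLatencyMs data.frame(modality, site, meanMs, sdMs): per-stimulus
#'   latency distribution at the primary site (and, for reference, the
#'   distant-site values the propagation model reproduces).
#' @slot evokedAreaMm2 data.frame(state, modality, areaMm2): evoked footprint.
#' @slot tauRiseS,tauDecayS calcium kernel time constants (s).
#' @slot paBandHz centre frequency of PA-state fluctuations (Hz), default 15.
#' @slot noiseSd additive Gaussian noise SD as a fraction of event amplitude.
#' @slot amplitude event amplitude in df/f units, default 1.
#' @slot directionJitterSd SD (rad) of wave direction around the AP axis.
#' @slot mlOriginRange range (mm) of the uniform ML jitter of wave origins.
#' @slot apOriginJitter half-range (mm) of AP jitter around the origin band.
#' @slot eventDurationS nominal up-state duration used by the LFP renderer (s).
#' @slot seed integer RNG seed; NA for unseeded.
#' @seealso [simConfig()]
#' @export
setClass("SimConfig",
  representation(state = "character", durationS = "numeric",
    fsTraceHz = "numeric", frameRateHz = "numeric",
    waveRatePerMin = "numeric", refractoryS = "numeric",
    anteriorOriginProb = "numeric", speedMeanMmS = "numeric",
    speedSdMmS = "numeric", pEvoke = "numeric", pRefractory = "numeric",
    evokedLatencyMs = "data.frame", evokedAreaMm2 = "data.frame",
    tauRiseS = "numeric", tauDecayS = "numeric", paBandHz = "numeric",
    noiseSd = "numeric", amplitude = "numeric",
    directionJitterSd = "numeric", mlOriginRange = "numeric",
    apOriginJitter = "numeric", eventDurationS = "numeric",
    seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@state %in% c("SWA", "PA"))
      msg <- c(msg, "state must be 'SWA' or 'PA'")
    nonneg <- c(durationS = object@durationS, waveRatePerMin = object@waveRatePerMin,
                refractoryS = object@refractoryS, speedSdMmS = object@speedSdMmS,
                noiseSd = object@noiseSd)
    if (any(!is.finite(nonneg)) || any(nonneg < 0))
      msg <- c(msg, "durations, rates and SDs must be finite and nonnegative")
    if (object@fsTraceHz <= 0 || object@frameRateHz <= 0)
      msg <- c(msg, "sampling rates must be positive")
    if (object@speedMeanMmS <= 0)
      msg <- c(msg, "speedMeanMmS must be positive")
    for (p in c(object@pEvoke, object@pRefractory, object@anteriorOriginProb))
      if (!is.finite(p) || p < 0 || p > 1)
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (object@tauRiseS <= 0 || object@tauDecayS <= 0)
      msg <- c(msg, "kernel time constants must be positive")
    if (length(msg)) msg else TRUE
  })

#' StimulusTrain: timed sensory stimuli
#'
#' @slot onsetsS strictly increasing stimulus (pulse) onset times, seconds.
#' @slot modality "visual" or "somatosensory".
#' @slot pulseMs pulse duration (ms), metadata.
#' @slot amplitudeMa stimulation amplitude (mA), metadata.
#' @slot isi free-text description of the inter-stimulus paradigm.
#' @seealso [generateStimulusTrain()]
#' @export
setClass("StimulusTrain",
  representation(onsetsS = "numeric", modality = "character",
                 pulseMs = "numeric", amplitudeMa = "numeric", isi = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@onsetsS) && any(diff(object@onsetsS) <= 0))
      msg <- c(msg, "onsets must be strictly increasing")
    if (any(!is.finite(object@onsetsS)))
      msg <- c(msg, "onsets must be finite")
    if (object@pulseMs <= 0) msg <- c(msg, "pulseMs must be positive")
    if (!object@modality %in% c("visual", "somatosensory"))
      msg <- c(msg, "modality must be 'visual' or 'somatosensory'")
    if (length(msg)) msg else TRUE
  })

#' GroundTruth: true events, per-site onsets and stimulus outcomes
#'
#' Container filled by [generateSpontaneousEvents()] and augmented by
#' [applyStimulusGating()]. Every renderer consumes it, and recovery tests
#' compare analysis output against it.
#'
#' @slot events data.frame with one row per wave: `time` (wave initiation, s),
#'   `originAp`, `originMl` (mm), `speedMmS`, `directionRad`, `evoked`
#'   (logical), `stimIndex` (index into the stimulus table, NA for
#'   spontaneous).
#' @slot siteOnsets named list of per-site wave onset times (s), strictly
#'   increasing.
#' @slot stimuli data.frame with one row per stimulus after gating: `onsetS`,
#'   `modality`, `timeSinceWaveS` (time since the most recent wave of any
#'   kind), `timeSinceSpontS`, `inRefractory`, `success`, `waveTimeS`,
#'   `latencyMs`.
#' @slot nMerged number of spontaneous events absorbed by evoked waves.
#' @slot geometry the [FieldGeometry-class] used.
#' @slot config the [SimConfig-class] used.
#' @slot empty TRUE when the duration was too short for a single event.
#' @export
setClass("GroundTruth",
  representation(events = "data.frame", siteOnsets = "list",
                 stimuli = "data.frame", nMerged = "integer",
                 geometry = "FieldGeometry", config = "SimConfig",
                 empty = "logical"),
  validity = function(object) {
    msg <- character()
    for (s in names(object@siteOnsets)) {
      o <- object@siteOnsets[[s]]
      if (length(o) > 1 && any(diff(o) <= 0))
        msg <- c(msg, sprintf("site onsets for %s must be strictly increasing", s))
    }
    if (nrow(object@events) && is.unsorted(object@events$time))
      msg <- c(msg, "event times must be sorted")
    if (length(msg)) msg else TRUE
  })

#' SampledTrace: regularly sampled single-site time series (virtual)
#'
#' @slot samples numeric signal samples.
#' @slot fsHz sampling rate (Hz).
#' @slot site recording site label.
#' @slot stateLabel "SWA", "PA" or "unknown".
#' @export
setClass("SampledTrace",
  representation(samples = "numeric", fsHz = "numeric",
                 site = "character", stateLabel = "character", "VIRTUAL"),
  validity = function(object) {
    msg <- character()
    if (length(object@fsHz) != 1L || object@fsHz <= 0)
      msg <- c(msg, "fsHz must be a single positive number")
    if (any(!is.finite(object@samples)))
      msg <- c(msg, "samples must be finite")
    if (length(msg)) msg else TRUE
  })

#' PhotometryTrace: fiber-photometry calcium signal
#'
#' @slot units "raw" (arbitrary fluorescence) or "dff" (relative change).
#' @seealso [SampledTrace-class], [normalizeDff()], [renderPhotometry()]
#' @export
setClass("PhotometryTrace", contains = "SampledTrace",
  representation(units = "character"),
  validity = function(object) {
    if (!object@units %in% c("raw", "dff"))
      "units must be 'raw' or 'dff'" else TRUE
  })

#' LfpTrace: local field potential signal
#'
#' @seealso [SampledTrace-class], [renderLfp()]
#' @export
setClass("LfpTrace", contains = "SampledTrace")

#' EventList: detected or ground-truth slow-wave events at one site
#'
#' @slot events data.frame with columns `onsetS`, `peakS`, `amplitude`,
#'   `durationS`; onsets strictly increasing, `peakS >= onsetS`,
#'   `durationS > 0`.
#' @slot site recording site label.
#' @seealso [detectEvents()]
#' @export
setClass("EventList",
  representation(events = "data.frame", site = "character"),
  validity = function(object) {
    ev <- object@events
    msg <- character()
    need <- c("onsetS", "peakS", "amplitude", "durationS")
    if (!all(need %in% names(ev)))
      return(paste("events needs columns", paste(need, collapse = ", ")))
    if (nrow(ev)) {
      if (any(diff(ev$onsetS) <= 0)) msg <- c(msg, "onsets must be strictly increasing")
      if (any(ev$peakS < ev$onsetS)) msg <- c(msg, "peakS must be >= onsetS")
      if (any(ev$durationS <= 0)) msg <- c(msg, "durationS must be positive")
    }
    if (length(msg)) msg else TRUE
  })

#' CalciumMovie: wide-field calcium movie
#'
#' @slot frames numeric array T x H x W.
#' @slot frameRateHz frame rate (Hz).
#' @slot t0S acquisition time of the first frame (s); stimulus-triggered
#'   averages carry negative `t0S` so that frame times are relative to the
#'   stimulus.
#' @slot geometry the [FieldGeometry-class]; H and W must match the field.
#' @slot units "raw" or "dff_pct" (percent df/f).
#' @slot aligned midline-aligned flag.
#' @seealso [renderWidefield()], [dffMovie()], [stimulusTriggeredAverage()]
#' @export
setClass("CalciumMovie",
  representation(frames = "array", frameRateHz = "numeric", t0S = "numeric",
                 geometry = "FieldGeometry", units = "character",
                 aligned = "logical"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@frames)
    if (length(d) != 3L) msg <- c(msg, "frames must be a T x H x W array")
    else {
      if (d[1] < 2L) msg <- c(msg, "movie needs at least 2 frames")
      hw <- fieldDim(object@geometry)
      if (d[2] != hw[1] || d[3] != hw[2])
        msg <- c(msg, "frame size must match the geometry")
    }
    if (object@frameRateHz <= 0) msg <- c(msg, "frameRateHz must be positive")
    if (!object@units %in% c("raw", "dff_pct")) msg <- c(msg, "bad units")
    if (length(msg)) msg else TRUE
  })

#' LatencyMap: per-pixel response-onset times
#'
#' @slot latencyS H x W matrix of onset latencies relative to the stimulus
#'   (s); NA where a pixel never crossed threshold.
#' @slot geometry the [FieldGeometry-class].
#' @seealso [onsetLatencyMap()]
#' @export
setClass("LatencyMap",
  representation(latencyS = "matrix", geometry = "FieldGeometry"),
  validity = function(object) {
    v <- object@latencyS[!is.na(object@latencyS)]
    if (length(v) && any(v < 0)) "latencies must be >= 0" else TRUE
  })

#' VelocityField: per-pixel propagation speed and direction
#'
#' @slot speedMmS H x W matrix (mm/s), NA where invalid.
#' @slot directionRad H x W matrix in (-pi, pi], 0 = anterior, +pi/2 lateral.
#' @slot valid logical H x W validity mask.
#' @slot geometry the [FieldGeometry-class].
#' @seealso [velocityField()], [meanVelocityVector()]
#' @export
setClass("VelocityField",
  representation(speedMmS = "matrix", directionRad = "matrix",
                 valid = "matrix", geometry = "FieldGeometry"),
  validity = function(object) {
    msg <- character()
    sp <- object@speedMmS[object@valid]
    if (length(sp) && (any(!is.finite(sp)) || any(sp <= 0)))
      msg <- c(msg, "valid speeds must be finite and positive")
    dr <- object@directionRad[object@valid]
    if (length(dr) && (any(dr <= -pi) || any(dr > pi)))
      msg <- c(msg, "directions must lie in (-pi, pi]")
    if (length(msg)) msg else TRUE
  })

#' ActivationHistogram: probability distribution of normalized activation
#'
#' @slot binEdges edges over normalized activation, length nBins + 1 spanning
#'   [0, 1].
#' @slot mass probability mass per bin (sums to 1).
#' @slot id recording/animal identifier.
#' @seealso [activationDistribution()]
#' @export
setClass("ActivationHistogram",
  representation(binEdges = "numeric", mass = "numeric", id = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@mass) != length(object@binEdges) - 1L)
      msg <- c(msg, "mass must have length(binEdges) - 1")
    if (any(object@mass < 0)) msg <- c(msg, "mass must be nonnegative")
    if (abs(sum(object@mass) - 1) > 1e-8) msg <- c(msg, "mass must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' Spectrogram: multitaper time-frequency power
#'
#' @slot timeS window-centre times (s).
#' @slot freqHz frequency bins (Hz), restricted to `fpass`.
#' @slot power time x frequency power matrix (signal units squared per Hz).
#' @slot params list(windowS, stepS, tw, k, fpass).
#' @seealso [multitaperSpectrogram()]
#' @export
setClass("Spectrogram",
  representation(timeS = "numeric", freqHz = "numeric", power = "matrix",
                 params = "list"),
  validity = function(object) {
    msg <- character()
    if (any(object@power < 0)) msg <- c(msg, "power must be nonnegative")
    if (nrow(object@power) != length(object@timeS) ||
        ncol(object@power) != length(object@freqHz))
      msg <- c(msg, "power must be time x frequency")
    fp <- object@params$fpass
    if (!is.null(fp) && length(object@freqHz) &&
        (min(object@freqHz) < fp[1] - 1e-9 || max(object@freqHz) > fp[2] + 1e-9))
      msg <- c(msg, "frequency bins must lie within fpass")
    if (length(msg)) msg else TRUE
  })

#' RefractoryEstimate: binned stimulus success rates and refractory period
#'
#' @slot binEdges contiguous bin edges from 0 (s), width `binS`.
#' @slot count stimuli per bin.
#' @slot successRate per-bin success rate (NA for empty bins).
#' @slot tauS estimated refractory period: lower edge of the first bin whose
#'   success rate strictly exceeds `criterion`; NA when no bin passes.
#' @slot criterion success-rate criterion (default 0.90).
#' @slot successWindowS window after the stimulus within which a wave counts
#'   as evoked (s).
#' @seealso [estimateRefractoryPeriod()]
#' @export
setClass("RefractoryEstimate",
  representation(binEdges = "numeric", count = "integer",
                 successRate = "numeric", tauS = "numeric",
                 criterion = "numeric", successWindowS = "numeric"),
  validity = function(object) {
    msg <- character()
    r <- object@successRate[!is.na(object@successRate)]
    if (length(r) && (any(r < 0) || any(r > 1)))
      msg <- c(msg, "success rates must lie in [0, 1]")
    if (abs(object@binEdges[1]) > 1e-12)
      msg <- c(msg, "bins must start at 0")
    if (length(msg)) msg else TRUE
  })

#' PolarDistribution: weighted circular distribution of directions
#'
#' @slot binEdges edges over (-pi, pi], length nBins + 1.
#' @slot mass weighted probability mass per bin (sums to 1).
#' @slot angles pooled angles (rad).
#' @slot weights pooled weights (e.g. speeds, mm/s).
#' @seealso [weightedPolarDistribution()]
#' @export
setClass("PolarDistribution",
  representation(binEdges = "numeric", mass = "numeric",
                 angles = "numeric", weights = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@weights < 0)) msg <- c(msg, "weights must be nonnegative")
    if (length(object@mass) != length(object@binEdges) - 1L)
      msg <- c(msg, "mass must have length(binEdges) - 1")
    if (sum(object@weights) > 0 && abs(sum(object@mass) - 1) > 1e-8)
      msg <- c(msg, "mass must sum to 1")
    if (length(msg)) msg else TRUE
  })

## ---- accessors -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("samples", "SampledTrace", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("fsHz", "SampledTrace", function(x) x@fsHz)
#' @rdname accessors
#' @export
setMethod("site", "SampledTrace", function(x) x@site)
#' @rdname accessors
#' @export
setMethod("site", "EventList", function(x) x@site)
#' @rdname accessors
#' @export
setMethod("stateLabel", "SampledTrace", function(x) x@stateLabel)
#' @rdname accessors
#' @export
setMethod("onsets", "StimulusTrain", function(x) x@onsetsS)
#' @rdname accessors
#' @export
setMethod("onsets", "EventList", function(x) x@events$onsetS)
#' @rdname accessors
#' @export
setMethod("modality", "StimulusTrain", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("events", "EventList", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("events", "GroundTruth", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("siteOnsets", "GroundTruth", function(x) x@siteOnsets)
#' @rdname accessors
#' @export
setMethod("stimulusTable", "GroundTruth", function(x) x@stimuli)
#' @rdname accessors
#' @export
setMethod("frames", "CalciumMovie", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("frameRateHz", "CalciumMovie", function(x) x@frameRateHz)
#' @rdname accessors
#' @export
setMethod("frameTimesS", "CalciumMovie",
  function(x) x@t0S + (seq_len(dim(x@frames)[1]) - 1L) / x@frameRateHz)
#' @rdname accessors
#' @export
setMethod("geometry", "CalciumMovie", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "GroundTruth", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "LatencyMap", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "VelocityField", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("latencies", "LatencyMap", function(x) x@latencyS)
#' @rdname accessors
#' @export
setMethod("speeds", "VelocityField", function(x) x@speedMmS)
#' @rdname accessors
#' @export
setMethod("directions", "VelocityField", function(x) x@directionRad)
#' @rdname accessors
#' @export
setMethod("validMask", "VelocityField", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("nEvents", "EventList", function(x) nrow(x@events))
#' @rdname accessors
#' @export
setMethod("nEvents", "GroundTruth", function(x) nrow(x@events))

#' @export
setMethod("length", "StimulusTrain", function(x) length(x@onsetsS))

## ---- show methods ----------------------------------------------------------

setMethod("show", "FieldGeometry", function(object) {
  hw <- fieldDim(object)
  cat(sprintf("FieldGeometry: AP [%.1f, %.1f] mm, ML [%.1f, %.1f] mm, pitch %.3g mm (%d x %d px)\n",
              object@apLim[1], object@apLim[2], object@mlLim[1], object@mlLim[2],
              object@pixelPitchMm, hw[1], hw[2]))
  if (nrow(object@sites))
    for (s in rownames(object@sites))
      cat(sprintf("  site %s: AP %.1f, ML %.1f\n", s,
                  object@sites[s, "ap"], object@sites[s, "ml"]))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig [%s]: %.0f s, fs %.0f Hz, frames %.0f Hz\n",
              object@state, object@durationS, object@fsTraceHz, object@frameRateHz))
  cat(sprintf("  waves %.1f/min, refractory %.1f s, anterior origin p=%.2f\n",
              object@waveRatePerMin, object@refractoryS, object@anteriorOriginProb))
  cat(sprintf("  speed %.1f +/- %.1f mm/s, pEvoke %.2f (inside refractory %.2f)\n",
              object@speedMeanMmS, object@speedSdMmS, object@pEvoke, object@pRefractory))
  cat(sprintf("  kernel rise %.0f ms / decay %.0f ms, noise SD %.2f, seed %s\n",
              1000 * object@tauRiseS, 1000 * object@tauDecayS, object@noiseSd,
              ifelse(is.na(object@seed), "unset", object@seed)))
})

setMethod("show", "StimulusTrain", function(object) {
  cat(sprintf("StimulusTrain: %d %s pulses (%s), %.0f-ms pulses\n",
              length(object@onsetsS), object@modality, object@isi, object@pulseMs))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth [%s]: %d events (%d evoked, %d spontaneous)\n",
              object@config@state, nrow(object@events),
              sum(object@events$evoked), sum(!object@events$evoked)))
  if (nrow(object@stimuli))
    cat(sprintf("  %d gated stimuli, %d successes, %d merged spontaneous events\n",
                nrow(object@stimuli), sum(object@stimuli$success), object@nMerged))
})

setMethod("show", "SampledTrace", function(object) {
  cat(sprintf("%s [%s, %s]: %.1f s at %.0f Hz\n", class(object),
              object@site, object@stateLabel,
              length(object@samples) / object@fsHz, object@fsHz))
})

setMethod("show", "EventList", function(object) {
  cat(sprintf("EventList [%s]: %d events\n", object@site, nrow(object@events)))
  if (nrow(object@events)) {
    cat(sprintf("  onsets %.2f .. %.2f s, median amplitude %.3g\n",
                min(object@events$onsetS), max(object@events$onsetS),
                stats::median(object@events$amplitude)))
  }
})

setMethod("show", "CalciumMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("CalciumMovie [%s]: %d frames of %d x %d at %.0f Hz (t0 %.2f s)\n",
              object@units, d[1], d[2], d[3], object@frameRateHz, object@t0S))
})

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf("Spectrogram: %d windows x %d freqs, %.0f-%.0f Hz, TW=%g K=%d\n",
              length(object@timeS), length(object@freqHz),
              object@params$fpass[1], object@params$fpass[2],
              object@params$tw, object@params$k))
})

setMethod("show", "RefractoryEstimate", function(object) {
  cat(sprintf("RefractoryEstimate: tau_r = %s s (criterion > %.0f%%, %.1f-s success window)\n",
              ifelse(is.na(object@tauS), "undefined", format(object@tauS)),
              100 * object@criterion, object@successWindowS))
  n <- length(object@count)
  show <- seq_len(min(n, 8L))
  cat("  bins:", paste(sprintf("[%.1f,%.1f) %s", object@binEdges[show],
      object@binEdges[show + 1L],
      ifelse(is.na(object@successRate[show]), "-",
             sprintf("%.2f", object@successRate[show]))), collapse = " "),
      if (n > 8L) "...\n" else "\n")
})

setMethod("show", "VelocityField", function(object) {
  n <- sum(object@valid)
  cat(sprintf("VelocityField: %d valid pixels", n))
  if (n) {
    mv <- meanVelocityVector(object)
    cat(sprintf(", mean vector %.1f mm/s at %.0f deg", mv["speedMmS"],
                180 / pi * mv["directionRad"]))
  }
  cat("\n")
})

setMethod("show", "PolarDistribution", function(object) {
  cat(sprintf("PolarDistribution: %d vectors in %d bins, circular mean %.0f deg\n",
              length(object@angles), length(object@mass),
              180 / pi * atan2(sum(object@weights * sin(object@angles)),
                               sum(object@weights * cos(object@angles)))))
})
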