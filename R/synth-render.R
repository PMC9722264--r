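#' Calcium impulse-response kernel
#'
#' Double-exponential kernel `(1 - exp(-t/tauRise)) * exp(-t/tauDecay)` for
#' `t >= 0`, normalized to unit peak.
#'
#' @param t times (s), may be negative (kernel is 0 there).
#' @param tauRiseS,tauDecayS rise and decay time constants (s).
#' @return kernel values, same length as `t`.
#' @export
calciumKernel <- function(t, tauRiseS = 0.05, tauDecayS = 1.0) {
  tPeak <- tauRiseS * log(1 + tauDecayS / tauRiseS)
  peak <- (1 - exp(-tPeak / tauRiseS)) * exp(-tPeak / tauDecayS)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (1 - exp(-t[pos] / tauRiseS)) * exp(-t[pos] / tauDecayS) / peak
  out
}

## add unit-peak kernels at the given onset times into a zero vector of n
## samples at fs; support limited to tauRise + 6*tauDecay
addKernels <- function(n, fs, onsetsS, tauRiseS, tauDecayS, amp = 1) {
  x <- numeric(n)
  supportN <- ceiling((tauRiseS + 6 * tauDecayS) * fs)
  for (o in onsetsS) {
    i0 <- floor(o * fs) + 1L
    if (i0 > n) next
    idx <- max(i0, 1L):min(i0 + supportN, n)
    tRel <- (idx - 1L) / fs - o
    x[idx] <- x[idx] + amp * calciumKernel(tRel, tauRiseS, tauDecayS)
  }
  x
}

## smoothed positive background used for the PA state: band-limited Gaussian
## noise offset to a positive working point
paBackground <- function(n, fs, sdRel, meanRel, loHz, hiHz) {
  z <- stats::rnorm(n)
  z <- fftBandpass(z, fs, loHz, hiHz)
  z <- z / stats::sd(z) * sdRel
  meanRel + z
}

#' Render fiber-photometry traces
#'
#' For the SWA state each site's raw trace is a constant baseline modulated by
#' the per-site sum of calcium kernels placed at that site's ground-truth wave
#' onsets, plus i.i.d. Gaussian noise (`noiseSd` of the event amplitude). The
#' PA state instead carries continuous band-limited fluctuations centred on
#' `paBandHz` plus a short-latency, fast-decaying evoked transient after every
#' stimulus. Raw traces are in arbitrary fluorescence units around `f0` so
#' that [normalizeDff()] recovers the df/f signal.
#'
#' @param groundTruth a [GroundTruth-class] (for PA, only the stimulus table
#'   is used).
#' @param geometry a [FieldGeometry-class]; defaults to the ground truth's.
#' @param config a [SimConfig-class]; defaults to the ground truth's.
#' @param f0 baseline fluorescence level (a.u.).
#' @param paEvokedLatencyMs latency of the PA evoked transient (ms).
#' @return named list of [PhotometryTrace-class], one per site.
#' @examples
#' gt <- generateSpontaneousEvents(simConfig("SWA", durationS = 60, seed = 1L))
#' tr <- renderPhotometry(gt)
#' tr$S1
#' @export
renderPhotometry <- function(groundTruth, geometry = groundTruth@geometry,
                             config = groundTruth@config, f0 = 100,
                             paEvokedLatencyMs = 25) {
  if (config@fsTraceHz < 100) stop("fsTraceHz must be at least 100 Hz")
  fs <- config@fsTraceHz
  n <- floor(config@durationS * fs)
  if (config@tauRiseS + 6 * config@tauDecayS > config@durationS)
    warning("calcium kernel support longer than the trace; truncating")
  withStageSeed(config, "photometry")
  out <- list()
  for (s in rownames(geometry@sites)) {
    if (config@state == "SWA") {
      act <- addKernels(n, fs, groundTruth@siteOnsets[[s]],
                        config@tauRiseS, config@tauDecayS, config@amplitude)
    } else {
      act <- config@amplitude *
        paBackground(n, fs, sdRel = 0.10, meanRel = 0.15,
                     loHz = max(config@paBandHz - 5, 1),
                     hiHz = config@paBandHz + 5)
      if (nrow(groundTruth@stimuli)) {
        tr <- groundTruth@stimuli$onsetS + paEvokedLatencyMs / 1000
        act <- act + addKernels(n, fs, tr, tauRiseS = 0.02, tauDecayS = 0.15,
                                amp = 0.3 * config@amplitude)
      }
    }
    noise <- stats::rnorm(n, 0, config@noiseSd * config@amplitude)
    raw <- f0 * (1 + act + noise)
    out[[s]] <- new("PhotometryTrace", samples = raw, fsHz = fs, site = s,
                    stateLabel = config@state, units = "raw")
  }
  out
}

## linear pixel indices (row-major within the H x W frame matrix, i.e.
## standard R column-major over [row, col]) of the nPix pixels nearest to a
## point; ties broken by index for determinism
nearestPixels <- function(geometry, ap, ml, nPix) {
  pc <- pixelCenters(geometry)
  d2 <- outer(pc$ap, pc$ml, function(a, m) (a - ap)^2 + (m - ml)^2)
  ord <- order(as.vector(d2), seq_along(d2))
  ord[seq_len(min(nPix, length(ord)))]
}

#' Render a wide-field calcium movie
#'
#' Every SWA wave is rendered as a plane wavefront crossing its footprint at
#' the event's speed and direction: the activation time of a pixel is the
#' event time plus the signed projection of (pixel - origin) onto the
#' propagation direction divided by the speed. Spontaneous waves span the full
#' field; evoked waves activate the `round(evokedArea / pitch^2)` pixels
#' nearest their initiating site (the whole field when the configured area
#' exceeds the field). In the PA state evoked responses are spatially confined
#' discs with a fast-decaying transient over a fluctuating background.
#' Per-pixel, per-frame Gaussian noise is added.
#'
#' @inheritParams renderPhotometry
#' @return A raw-intensity [CalciumMovie-class].
#' @export
renderWidefield <- function(groundTruth, geometry = groundTruth@geometry,
                            config = groundTruth@config, f0 = 100,
                            paEvokedLatencyMs = 25) {
  if (config@frameRateHz < 10) stop("frameRateHz must be at least 10 Hz")
  hw <- fieldDim(geometry)
  if (hw[1] < 2 || hw[2] < 2)
    stop("pixel pitch incompatible with the field extent")
  fr <- config@frameRateHz
  nT <- floor(config@durationS * fr)
  tFrames <- (seq_len(nT) - 1L) / fr
  nPixField <- hw[1] * hw[2]
  pc <- pixelCenters(geometry)
  apGrid <- matrix(pc$ap, hw[1], hw[2])
  mlGrid <- matrix(pc$ml, hw[1], hw[2], byrow = TRUE)
  withStageSeed(config, "widefield")
  act <- matrix(0, nT, nPixField)
  addEventToMovie <- function(ev, footprint, tauRiseS, tauDecayS, amp) {
    aTimes <- ev$time + travelTimeS(apGrid[footprint], mlGrid[footprint],
                                    ev$originAp, ev$originMl,
                                    ev$directionRad, ev$speedMmS)
    fLo <- max(1L, floor(min(aTimes) * fr) + 1L)
    fHi <- min(nT, ceiling((max(aTimes) + tauRiseS + 6 * tauDecayS) * fr) + 1L)
    if (fLo > fHi) return(invisible(NULL))
    dt <- outer(tFrames[fLo:fHi], aTimes, `-`)
    act[fLo:fHi, footprint] <<- act[fLo:fHi, footprint] +
      amp * calciumKernel(dt, tauRiseS, tauDecayS)
    invisible(NULL)
  }
  if (config@state == "SWA") {
    ev <- groundTruth@events
    for (i in seq_len(nrow(ev))) {
      if (ev$evoked[i]) {
        modal <- groundTruth@stimuli$modality[ev$stimIndex[i]]
        nPix <- round(evokedArea(config, modal) / geometry@pixelPitchMm^2)
        fp <- nearestPixels(geometry, ev$originAp[i], ev$originMl[i], nPix)
      } else fp <- seq_len(nPixField)
      addEventToMovie(ev[i, ], fp, config@tauRiseS, config@tauDecayS,
                      config@amplitude)
    }
  } else {
    g <- config@amplitude * paBackground(nT, fr, sdRel = 0.10, meanRel = 0.15,
                                         loHz = 0.1, hiHz = min(2, fr / 4))
    act <- act + g  # global PA fluctuation shared by all pixels
    st <- groundTruth@stimuli
    for (i in seq_len(nrow(st))) {
      nPix <- round(evokedArea(config, st$modality[i]) / geometry@pixelPitchMm^2)
      sc <- siteCoords(geometry, primaryLatency(config, st$modality[i])$site)
      fp <- nearestPixels(geometry, sc["ap"], sc["ml"], nPix)
      evRow <- data.frame(time = st$onsetS[i] + paEvokedLatencyMs / 1000,
                          originAp = sc["ap"], originMl = sc["ml"],
                          speedMmS = 1e6, directionRad = 0)
      addEventToMovie(evRow, fp, tauRiseS = 0.02, tauDecayS = 0.15,
                      amp = 0.5 * config@amplitude)
    }
  }
  noise <- matrix(stats::rnorm(nT * nPixField, 0,
                               config@noiseSd * config@amplitude),
                  nT, nPixField)
  raw <- f0 * (1 + act + noise)
  frames <- array(raw, dim = c(nT, hw[["rows"]], hw[["cols"]]))
  new("CalciumMovie", frames = frames, frameRateHz = fr, t0S = 0,
      geometry = geometry, units = "raw", aligned = TRUE)
}

## Hann-windowed gamma-band packet
gammaPacket <- function(n, fs, t0, freqHz = 80, durS = 0.06, amp = 1) {
  i0 <- floor(t0 * fs) + 1L
  m <- round(durS * fs)
  if (i0 > n || m < 2) return(numeric(n))
  idx <- i0:min(i0 + m - 1L, n)
  tRel <- (idx - i0) / fs
  x <- numeric(n)
  x[idx] <- amp * sin(2 * pi * freqHz * tRel) *
    0.5 * (1 - cos(2 * pi * tRel / durS))
  x
}

#' Render an LFP-like signal
#'
#' SWA: a near-flat low-noise baseline; each wave contributes a large
#' stereotyped delta-band onset deflection (damped 3-Hz transient) followed by
#' sustained broadband (0.5-200 Hz, with an extra band around 40 Hz) activity
#' over the nominal up-state duration. PA: continuous narrowband activity
#' around `paBandHz` over pink noise. In both states every stimulus adds a
#' brief gamma-band packet (80 Hz, 60 ms) shortly after its onset.
#'
#' @param groundTruth a [GroundTruth-class].
#' @param config a [SimConfig-class]; defaults to the ground truth's.
#' @param site which site's wave onsets to use.
#' @param amp overall amplitude scale (a.u.).
#' @return An [LfpTrace-class].
#' @export
renderLfp <- function(groundTruth, config = groundTruth@config,
                      site = "V1", amp = 1) {
  fs <- config@fsTraceHz
  if (fs < 500) stop("LFP rendering requires fs >= 500 Hz")
  n <- floor(config@durationS * fs)
  withStageSeed(config, paste0("lfp", site))
  t <- (seq_len(n) - 1L) / fs
  if (config@state == "SWA") {
    broadband <- fftBandpass(stats::rnorm(n), fs, 0.5, min(200, fs / 2 - 1))
    broadband <- broadband / stats::sd(broadband)
    band40 <- fftBandpass(stats::rnorm(n), fs, 35, 45)
    band40 <- band40 / stats::sd(band40)
    env <- numeric(n)
    defl <- numeric(n)
    for (o in groundTruth@siteOnsets[[site]]) {
      i0 <- floor(o * fs) + 1L
      if (i0 > n) next
      iDur <- i0:min(i0 + round(config@eventDurationS * fs), n)
      env[iDur] <- pmax(env[iDur], 1)
      iDef <- i0:min(i0 + round(0.6 * fs), n)
      tr <- (iDef - i0) / fs
      defl[iDef] <- defl[iDef] + 5 * sin(2 * pi * 3 * tr) * exp(-tr / 0.2)
    }
    x <- amp * (0.05 * broadband + env * (broadband + 0.7 * band40) + defl)
  } else {
    narrow <- fftBandpass(stats::rnorm(n), fs, config@paBandHz - 2,
                          config@paBandHz + 2)
    narrow <- narrow / stats::sd(narrow)
    pink <- pinkNoise(n)
    x <- amp * (0.5 * narrow + 0.15 * pink)
  }
  if (nrow(groundTruth@stimuli)) {
    ## the fast primary response is confined to the stimulated modality's
    ## primary sensory area; distant sites receive only the propagated wave
    for (i in seq_len(nrow(groundTruth@stimuli))) {
      primary <- primaryLatency(config, groundTruth@stimuli$modality[i])$site
      if (identical(primary, site))
        x <- x + gammaPacket(n, fs, groundTruth@stimuli$onsetS[i] + 0.005,
                             amp = 1.2 * amp)
    }
  }
  new("LfpTrace", samples = x, fsHz = fs, site = site,
      stateLabel = config@state)
}

## 1/f-amplitude noise via spectral shaping, unit variance
pinkNoise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index
  spec <- spec / sqrt(f)
  out <- Re(stats::fft(spec, inverse = TRUE)) / n
  out / stats::sd(out)
}
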