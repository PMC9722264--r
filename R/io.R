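## key=value header lines ("# key: value") used by the CSV readers/writers
readHeaderMeta <- function(path) {
  lines <- readLines(path, n = 20)
  lines <- lines[startsWith(lines, "# ")]
  meta <- list()
  for (ln in lines) {
    kv <- sub("^# ", "", ln)
    i <- regexpr(":", kv, fixed = TRUE)
    if (i > 0)
      meta[[trimws(substr(kv, 1, i - 1))]] <- trimws(substr(kv, i + 1, nchar(kv)))
  }
  meta
}

#' Write / read a sampled trace as CSV
#'
#' Plain CSV with a `time_s, signal` body and `# key: value` header lines
#' carrying the sampling rate, site, state and units.
#'
#' @param trace a [PhotometryTrace-class] or [LfpTrace-class].
#' @param path file path.
#' @return `writeTraceCsv` returns `path` invisibly; `readTraceCsv` returns
#'   the reconstructed trace object.
#' @export
writeTraceCsv <- function(trace, path) {
  stopifnot(is(trace, "SampledTrace"))
  meta <- c(sprintf("# class: %s", class(trace)),
            sprintf("# fs_hz: %.10g", fsHz(trace)),
            sprintf("# site: %s", site(trace)),
            sprintf("# state: %s", stateLabel(trace)))
  if (is(trace, "PhotometryTrace"))
    meta <- c(meta, sprintf("# units: %s", trace@units))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  x <- samples(trace)
  utils::write.csv(data.frame(time_s = (seq_along(x) - 1) / fsHz(trace),
                              signal = x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path) {
  meta <- readHeaderMeta(path)
  d <- utils::read.csv(path, comment.char = "#")
  cls <- meta$class %||% "PhotometryTrace"
  args <- list(cls, samples = d$signal, fsHz = as.numeric(meta$fs_hz),
               site = meta$site %||% "unknown",
               stateLabel = meta$state %||% "unknown")
  if (cls == "PhotometryTrace") args$units <- meta$units %||% "raw"
  do.call(new, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a stimulus log as CSV
#'
#' Columns `onset_s, modality, pulse_ms`.
#'
#' @param stimuli a [StimulusTrain-class].
#' @param path file path.
#' @export
writeStimulusCsv <- function(stimuli, path) {
  stopifnot(is(stimuli, "StimulusTrain"))
  utils::write.csv(data.frame(onset_s = onsets(stimuli),
                              modality = modality(stimuli),
                              pulse_ms = stimuli@pulseMs),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeStimulusCsv
#' @export
readStimulusCsv <- function(path) {
  d <- utils::read.csv(path)
  new("StimulusTrain", onsetsS = as.numeric(d$onset_s), modality = as.character(d$modality[1]),
      pulseMs = as.numeric(d$pulse_ms[1]), amplitudeMa = 1,
      isi = "from file")
}

#' Write / read ground truth as JSON
#'
#' Serializes the event table, per-site onsets and the stimulus table; the
#' geometry and configuration are stored alongside so the object round-trips.
#'
#' @param groundTruth a [GroundTruth-class].
#' @param path file path.
#' @export
writeGroundTruthJson <- function(groundTruth, path) {
  g <- groundTruth@geometry
  cfg <- groundTruth@config
  obj <- list(events = groundTruth@events, siteOnsets = groundTruth@siteOnsets,
              stimuli = groundTruth@stimuli, nMerged = groundTruth@nMerged,
              empty = groundTruth@empty,
              geometry = list(apLim = g@apLim, mlLim = g@mlLim,
                              pixelPitchMm = g@pixelPitchMm,
                              sites = as.data.frame(cbind(site = rownames(g@sites),
                                                          as.data.frame(g@sites)))),
              config = configAsList(cfg))
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeGroundTruthJson
#' @export
readGroundTruthJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sitesDf <- as.data.frame(obj$geometry$sites)
  sm <- cbind(ap = as.numeric(sitesDf$ap), ml = as.numeric(sitesDf$ml))
  rownames(sm) <- sitesDf$site
  geom <- fieldGeometry(obj$geometry$apLim, obj$geometry$mlLim,
                        obj$geometry$pixelPitchMm, sm)
  cl <- obj$config
  if (is.null(cl$seed) || !length(cl$seed)) cl$seed <- NA_integer_
  cl$evokedLatencyMs <- as.data.frame(cl$evokedLatencyMs)
  cl$evokedAreaMm2 <- as.data.frame(cl$evokedAreaMm2)
  cfg <- do.call(simConfig, cl)
  ev <- as.data.frame(obj$events)
  if (!nrow(ev))
    ev <- data.frame(time = numeric(), originAp = numeric(),
                     originMl = numeric(), speedMmS = numeric(),
                     directionRad = numeric(), evoked = logical(),
                     stimIndex = integer())
  else ev <- as.data.frame(lapply(ev, unlist), stringsAsFactors = FALSE)
  ev$stimIndex <- as.integer(ev$stimIndex)
  st <- as.data.frame(obj$stimuli)
  new("GroundTruth", events = ev,
      siteOnsets = lapply(obj$siteOnsets, as.numeric),
      stimuli = st, nMerged = as.integer(obj$nMerged),
      geometry = geom, config = cfg, empty = isTRUE(obj$empty))
}

## SimConfig <-> plain list (YAML/JSON-safe)
configAsList <- function(cfg) {
  list(state = cfg@state, durationS = cfg@durationS, seed = cfg@seed,
       fsTraceHz = cfg@fsTraceHz, frameRateHz = cfg@frameRateHz,
       waveRatePerMin = cfg@waveRatePerMin, refractoryS = cfg@refractoryS,
       anteriorOriginProb = cfg@anteriorOriginProb,
       speedMeanMmS = cfg@speedMeanMmS, speedSdMmS = cfg@speedSdMmS,
       pEvoke = cfg@pEvoke, pRefractory = cfg@pRefractory,
       evokedLatencyMs = cfg@evokedLatencyMs, evokedAreaMm2 = cfg@evokedAreaMm2,
       tauRiseS = cfg@tauRiseS, tauDecayS = cfg@tauDecayS,
       paBandHz = cfg@paBandHz, noiseSd = cfg@noiseSd,
       amplitude = cfg@amplitude, directionJitterSd = cfg@directionJitterSd,
       mlOriginRange = cfg@mlOriginRange, apOriginJitter = cfg@apOriginJitter,
       eventDurationS = cfg@eventDurationS)
}

#' Write / read a generator configuration as YAML
#'
#' @param config a [SimConfig-class].
#' @param path file path.
#' @export
writeConfigYaml <- function(config, path) {
  lst <- configAsList(config)
  lst$evokedLatencyMs <- as.list(lst$evokedLatencyMs)
  lst$evokedAreaMm2 <- as.list(lst$evokedAreaMm2)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeConfigYaml
#' @export
readConfigYaml <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$evokedLatencyMs <- as.data.frame(lst$evokedLatencyMs)
  lst$evokedAreaMm2 <- as.data.frame(lst$evokedAreaMm2)
  if (is.null(lst$seed)) lst$seed <- NA_integer_
  do.call(simConfig, lst)
}

#' Write / read a movie as multi-page TIFF
#'
#' Frames are stored as 32-bit float TIFF pages scaled to [0, 1]; the scaling
#' range and acquisition metadata go to a JSON sidecar (`<path>.json`) so the
#' movie round-trips exactly.
#'
#' @param movie a [CalciumMovie-class].
#' @param path file path (`.tif`).
#' @export
writeMovieTiff <- function(movie, path) {
  stopifnot(is(movie, "CalciumMovie"))
  f <- frames(movie)
  rng <- range(f, finite = TRUE)
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1
  pages <- lapply(seq_len(dim(f)[1]), function(i)
    (f[i, , ] - rng[1]) / (rng[2] - rng[1]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  g <- geometry(movie)
  meta <- list(frameRateHz = frameRateHz(movie), t0S = movie@t0S,
               units = movie@units, aligned = movie@aligned,
               range = rng, apLim = g@apLim, mlLim = g@mlLim,
               pixelPitchMm = g@pixelPitchMm,
               sites = data.frame(site = rownames(g@sites), ap = g@sites[, "ap"],
                                  ml = g@sites[, "ml"]))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname writeMovieTiff
#' @export
readMovieTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sm <- cbind(ap = meta$sites$ap, ml = meta$sites$ml)
  rownames(sm) <- meta$sites$site
  geom <- fieldGeometry(meta$apLim, meta$mlLim, meta$pixelPitchMm, sm)
  rng <- meta$range
  f <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages))
    f[i, , ] <- pages[[i]] * (rng[2] - rng[1]) + rng[1]
  new("CalciumMovie", frames = f, frameRateHz = meta$frameRateHz,
      t0S = meta$t0S, geometry = geom, units = meta$units,
      aligned = isTRUE(meta$aligned))
}

#' Write / read an event list as CSV
#'
#' @param eventList an [EventList-class].
#' @param path file path.
#' @export
writeEventsCsv <- function(eventList, path) {
  stopifnot(is(eventList, "EventList"))
  d <- events(eventList)
  d$site <- site(eventList)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsCsv
#' @export
readEventsCsv <- function(path) {
  d <- utils::read.csv(path)
  s <- if ("site" %in% names(d) && nrow(d)) as.character(d$site[1]) else "unknown"
  new("EventList",
      events = d[, c("onsetS", "peakS", "amplitude", "durationS"), drop = FALSE],
      site = s)
}
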