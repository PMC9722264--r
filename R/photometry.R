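#' Normalize a raw photometry trace to df/f
#'
#' Divides the raw trace by the mean over a baseline window and subtracts 1,
#' yielding the relative fluorescence change df/f.
#'
#' @param trace a raw [PhotometryTrace-class].
#' @param baselineWindowS numeric(2), start and end (s) of the baseline
#'   window; must lie within the trace and span at least `minLengthS`.
#' @param minLengthS minimum admissible baseline length (s), default 0.5.
#' @return a df/f [PhotometryTrace-class].
#' @examples
#' tr <- new("PhotometryTrace", samples = rep(2, 2000), fsHz = 2000,
#'           site = "S1", stateLabel = "unknown", units = "raw")
#' range(samples(normalizeDff(tr, c(0, 1))))  # all zero
#' @export
normalizeDff <- function(trace, baselineWindowS, minLengthS = 0.5) {
  stopifnot(is(trace, "PhotometryTrace"))
  fs <- fsHz(trace)
  n <- length(samples(trace))
  w <- sort(baselineWindowS)
  if (diff(w) < minLengthS)
    stop(sprintf("baseline window must span at least %.2f s", minLengthS))
  i0 <- max(1L, floor(w[1] * fs) + 1L)
  i1 <- min(n, ceiling(w[2] * fs))
  if (i0 >= i1 || w[1] < 0 || w[2] > n / fs)
    stop("baseline window must lie within the trace")
  m <- mean(samples(trace)[i0:i1])
  if (!is.finite(m) || m <= 0)
    stop("degenerate baseline: mean must be positive")
  new("PhotometryTrace", samples = samples(trace) / m - 1, fsHz = fs,
      site = site(trace), stateLabel = stateLabel(trace), units = "dff")
}

#' Pick a quiet baseline window automatically
#'
#' Slides windows of `lengthS` across the trace and returns the one with the
#' lowest combined mean and variability of the (lightly smoothed) signal,
#' i.e. a silent period. Automates the manual baseline selection used in
#' practice.
#'
#' @param trace a [PhotometryTrace-class].
#' @param lengthS window length (s), default 1.
#' @param stepS slide step (s).
#' @return numeric(2): start and end (s) of the selected window.
#' @export
pickBaselineWindow <- function(trace, lengthS = 1, stepS = 0.5) {
  x <- samples(trace)
  fs <- fsHz(trace)
  wN <- round(lengthS * fs)
  if (wN >= length(x)) stop("trace shorter than the baseline window")
  starts <- seq(1L, length(x) - wN, by = max(1L, round(stepS * fs)))
  sm <- stats::filter(x, rep(1 / 64, 64), sides = 2)
  sm[is.na(sm)] <- x[is.na(sm)]
  score <- vapply(starts, function(i) {
    seg <- sm[i:(i + wN - 1L)]
    mean(seg) + stats::sd(seg)
  }, numeric(1))
  i <- starts[which.min(score)]
  c((i - 1L) / fs, (i - 1L + wN) / fs)
}

#' Gaussian low-pass filter
#'
#' Zero-phase smoothing with a Gaussian kernel whose amplitude response has
#' its -3 dB point at `cutoffHz` (sigma = sqrt(ln 2) / (2 pi fc)). Edges are
#' handled by replicate padding; the kernel sums to one so DC is preserved.
#'
#' @param trace a [PhotometryTrace-class] (or [LfpTrace-class]).
#' @param cutoffHz -3 dB cutoff frequency (Hz), default 20; must be below
#'   Nyquist.
#' @return the filtered trace, same class and units.
#' @export
lowpassGaussian <- function(trace, cutoffHz = 20) {
  stopifnot(is(trace, "SampledTrace"))
  fs <- fsHz(trace)
  if (cutoffHz >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (cutoffHz <= 0) stop("cutoff must be positive")
  sigmaN <- sqrt(log(2)) / (2 * pi * cutoffHz) * fs
  half <- max(1L, ceiling(4 * sigmaN))
  k <- stats::dnorm(seq(-half, half), sd = sigmaN)
  k <- k / sum(k)
  x <- samples(trace)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  y <- stats::filter(xp, k, method = "convolution", sides = 2)
  y <- as.numeric(y)[(half + 1):(half + length(x))]
  initialize(trace, samples = y)
}

## iteratively refined baseline statistics from the sub-threshold mask;
## median/MAD so that event rises and decay tails inside the mask do not
## inflate the noise estimate
baselineStats <- function(x, kSd, maxIter = 10) {
  m <- stats::median(x); s <- stats::mad(x)
  if (!is.finite(s) || s == 0) s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    return(list(mean = m, sd = 0, mask = rep(TRUE, length(x))))
  for (i in seq_len(maxIter)) {
    mask <- x < m + kSd * s
    if (!any(mask)) stop("no sub-threshold samples: cannot estimate a baseline")
    m2 <- stats::median(x[mask]); s2 <- stats::mad(x[mask])
    if (!is.finite(s2)) s2 <- 0
    if (s2 == 0) {
      ## degenerate (e.g. noise-free) baseline: fall back to the plain SD of
      ## the masked samples, then to a tiny fraction of the dynamic range
      s2 <- stats::sd(x[mask])
      if (!is.finite(s2) || s2 == 0) s2 <- 1e-9 * diff(range(x))
    }
    if (abs(m2 - m) < 1e-12 && abs(s2 - s) < 1e-12) break
    m <- m2; s <- s2
  }
  list(mean = m, sd = s, mask = mask)
}

#' Detect slow-wave events in a df/f trace
#'
#' Onsets are threshold crossings of `baseline mean + kSd * baseline SD`,
#' where the baseline statistics come from an iteratively refined
#' sub-threshold mask; a crossing only counts when the signal stays above
#' threshold for at least `minDurationS`, and events closer than
#' `minSeparationS` are merged. Because consecutive slow waves can ride on
#' each other's calcium decay without returning below threshold, a
#' supra-threshold epoch is additionally split wherever the derivative
#' crosses its own threshold again (`splitOnRise`); each secondary rise marks
#' a new event onset at the start of its positive-derivative run. Baseline
#' statistics are median/MAD-based so that event tails inside the
#' sub-threshold mask do not inflate the noise estimate.
#'
#' @param trace a df/f, low-pass-filtered [PhotometryTrace-class].
#' @param kSd threshold in baseline SDs, default 3.
#' @param minDurationS minimum supra-threshold duration (s), default 0.2.
#' @param minSeparationS events closer than this are merged (s), default 1.
#' @param splitOnRise split chained events at secondary derivative rises.
#' @param riseKSd derivative threshold in derivative-baseline SDs.
#' @return an [EventList-class] (onset, peak, amplitude, duration per event).
#' @export
detectEvents <- function(trace, kSd = 3.0, minDurationS = 0.2,
                         minSeparationS = 1.0, splitOnRise = TRUE,
                         riseKSd = 5.0) {
  stopifnot(is(trace, "SampledTrace"))
  x <- samples(trace)
  fs <- fsHz(trace)
  emptyEv <- data.frame(onsetS = numeric(), peakS = numeric(),
                        amplitude = numeric(), durationS = numeric())
  bs <- baselineStats(x, kSd)
  if (bs$sd == 0)
    return(new("EventList", events = emptyEv, site = site(trace)))
  thr <- bs$mean + kSd * bs$sd
  above <- x > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  epochs <- data.frame(start = starts[r$values], end = ends[r$values])
  minN <- round(minDurationS * fs)
  epochs <- epochs[epochs$end - epochs$start + 1L >= minN, , drop = FALSE]
  if (!nrow(epochs))
    return(new("EventList", events = emptyEv, site = site(trace)))
  ## merge epochs separated by less than minSeparationS
  mergedStart <- epochs$start[1]; mergedEnd <- epochs$end[1]
  keepS <- c(); keepE <- c()
  gapN <- round(minSeparationS * fs)
  for (i in seq_len(nrow(epochs))[-1]) {
    if (epochs$start[i] - mergedEnd <= gapN) {
      mergedEnd <- epochs$end[i]
    } else {
      keepS <- c(keepS, mergedStart); keepE <- c(keepE, mergedEnd)
      mergedStart <- epochs$start[i]; mergedEnd <- epochs$end[i]
    }
  }
  keepS <- c(keepS, mergedStart); keepE <- c(keepE, mergedEnd)
  ## derivative statistics for within-epoch splitting
  d <- c(0, diff(x)) * fs
  sdD <- stats::sd(d[bs$mask])
  dThr <- riseKSd * sdD
  onsetsIdx <- list()
  for (e in seq_along(keepS)) {
    i0 <- keepS[e]; i1 <- keepE[e]
    eOnsets <- i0
    if (splitOnRise && sdD > 0 && i1 - i0 > gapN) {
      seg <- d[i0:i1]
      up <- which(seg[-1] > dThr & seg[-length(seg)] <= dThr) + i0
      for (u in up) {
        uu <- u
        while (uu > i0 && d[uu - 1L] > 0) uu <- uu - 1L
        if (uu - max(eOnsets) > gapN) eOnsets <- c(eOnsets, uu)
      }
    }
    onsetsIdx <- c(onsetsIdx, list(list(onsets = eOnsets, end = i1)))
  }
  rows <- list()
  for (ep in onsetsIdx) {
    os <- ep$onsets
    for (j in seq_along(os)) {
      segEnd <- if (j < length(os)) os[j + 1L] - 1L else ep$end
      pk <- os[j] - 1L + which.max(x[os[j]:segEnd])
      lowLevel <- bs$mean + bs$sd
      after <- which(x[pk:segEnd] < lowLevel)
      evEnd <- if (length(after)) pk + after[1] - 1L else segEnd
      rows[[length(rows) + 1L]] <- data.frame(
        onsetS = (os[j] - 1L) / fs, peakS = (pk - 1L) / fs,
        amplitude = x[pk] - bs$mean,
        durationS = max(evEnd - os[j], 1L) / fs)
    }
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$onsetS), , drop = FALSE]
  ## guard against duplicated onsets after refinement
  ev <- ev[!duplicated(ev$onsetS), , drop = FALSE]
  rownames(ev) <- NULL
  new("EventList", events = ev, site = site(trace))
}

#' Per-stimulus response latency (trace input)
#'
#' `mode = "swa_onset"`: latency from each stimulus to the next detected
#' slow-wave onset (events detected with [detectEvents()] when a trace is
#' supplied); missing (NA) when no onset occurs within `searchLimitS`.
#' `mode = "pa_peak"`: latency to the maximum df/f within `windowS` after the
#' stimulus. Stimuli whose window extends past the end of the trace are
#' skipped and flagged.
#'
#' @param x a [PhotometryTrace-class] or [EventList-class] (the latter only
#'   for `mode = "swa_onset"`).
#' @param stimuli a [StimulusTrain-class] or numeric onset vector (s).
#' @param mode "swa_onset" or "pa_peak".
#' @param windowS window for `pa_peak` (s), default 2.
#' @param searchLimitS maximum lookahead for `swa_onset` (s), default 5.
#' @param ... unused.
#' @return data.frame(stimulusS, latencyS, flag) with flag in
#'   `ok`/`missing`/`truncated`.
#' @name responseLatency
NULL

responseLatencyCore <- function(eventOnsets, stimOn, traceEndS, mode,
                                windowS, searchLimitS, trace = NULL) {
  out <- data.frame(stimulusS = stimOn, latencyS = NA_real_, flag = "ok",
                    stringsAsFactors = FALSE)
  for (i in seq_along(stimOn)) {
    s <- stimOn[i]
    if (mode == "pa_peak") {
      if (s + windowS > traceEndS) { out$flag[i] <- "truncated"; next }
      fs <- fsHz(trace)
      i0 <- floor(s * fs) + 1L
      i1 <- min(length(samples(trace)), floor((s + windowS) * fs))
      seg <- samples(trace)[i0:i1]
      out$latencyS[i] <- (i0 - 1L + which.max(seg) - 1L) / fs - s
    } else {
      if (s > traceEndS) { out$flag[i] <- "truncated"; next }
      nxt <- eventOnsets[eventOnsets > s]
      if (length(nxt) && nxt[1] - s <= searchLimitS) {
        out$latencyS[i] <- nxt[1] - s
      } else out$flag[i] <- "missing"
    }
  }
  out
}

#' @rdname responseLatency
#' @export
setMethod("responseLatency", "PhotometryTrace",
  function(x, stimuli, mode = c("swa_onset", "pa_peak"), windowS = 2,
           searchLimitS = 5, ...) {
    mode <- match.arg(mode)
    stimOn <- if (is(stimuli, "StimulusTrain")) onsets(stimuli) else stimuli
    endS <- length(samples(x)) / fsHz(x)
    ev <- if (mode == "swa_onset") onsets(detectEvents(x, ...)) else numeric()
    responseLatencyCore(ev, stimOn, endS, mode, windowS, searchLimitS, trace = x)
  })

#' @rdname responseLatency
#' @export
setMethod("responseLatency", "EventList",
  function(x, stimuli, mode = "swa_onset", windowS = 2, searchLimitS = 5,
           traceEndS = Inf, ...) {
    if (mode != "swa_onset")
      stop("EventList input supports mode = 'swa_onset' only")
    stimOn <- if (is(stimuli, "StimulusTrain")) onsets(stimuli) else stimuli
    responseLatencyCore(onsets(x), stimOn, traceEndS, "swa_onset", windowS,
                        searchLimitS)
  })

#' Shuffle stimulus onsets for a jitter control
#'
#' Each onset is displaced by an independent uniform draw over a total range
#' of `jitterRangeS` centred on the true onset (i.e. +/- jitterRangeS / 2),
#' then re-sorted. The stimulus count is preserved.
#'
#' @param stimuli a [StimulusTrain-class].
#' @param jitterRangeS total jitter range (s), default 2.
#' @param seed optional RNG seed.
#' @return a shuffled [StimulusTrain-class].
#' @export
shuffleOnsets <- function(stimuli, jitterRangeS = 2.0, seed = NULL) {
  stopifnot(is(stimuli, "StimulusTrain"))
  if (jitterRangeS <= 0) stop("jitterRangeS must be positive")
  if (!is.null(seed)) set.seed(seed)
  o <- onsets(stimuli) +
    stats::runif(length(stimuli), -jitterRangeS / 2, jitterRangeS / 2)
  initialize(stimuli, onsetsS = sort(o),
             isi = paste(stimuli@isi, "(shuffled)"))
}

#' Normalized cross-correlogram of two traces
#'
#' Sign convention: a positive peak lag means `traceA` leads `traceB`.
#'
#' @param traceA,traceB [SampledTrace-class] objects at the same sampling
#'   rate, overlapping for at least `2 * maxLagS`.
#' @param maxLagS maximum lag (s).
#' @return list(lagS, correlation, peakLagS, peakValue).
#' @export
crossCorrelogram <- function(traceA, traceB, maxLagS) {
  stopifnot(is(traceA, "SampledTrace"), is(traceB, "SampledTrace"))
  if (fsHz(traceA) != fsHz(traceB)) stop("traces must share a sampling rate")
  fs <- fsHz(traceA)
  n <- min(length(samples(traceA)), length(samples(traceB)))
  if (n / fs < 2 * maxLagS) stop("overlap must be at least 2 * maxLagS")
  a <- samples(traceA)[seq_len(n)]
  b <- samples(traceB)[seq_len(n)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero-variance input")
  lagN <- round(maxLagS * fs)
  ## ccf(b, a) at lag k = cor(b[t + k], a[t]): peaks at +d when b lags a by d
  cc <- stats::ccf(b, a, lag.max = lagN, plot = FALSE, demean = TRUE)
  lags <- as.numeric(cc$lag) / fs
  r <- as.numeric(cc$acf)
  iPk <- which.max(r)
  list(lagS = lags, correlation = r, peakLagS = lags[iPk], peakValue = r[iPk])
}

#' Inter-regional event delays and lead/lag structure
#'
#' Matches events across two sites greedily by onset proximity (closest pairs
#' first) within `matchWindowS`, then reports per-pair delays
#' (onset at B - onset at A) and the fraction of pairs in which site A leads.
#'
#' @param eventsA,eventsB [EventList-class] objects (A is the reference,
#'   e.g. S1).
#' @param matchWindowS maximum onset separation for a match (s), default 1.
#' @return list(delaysS, leaderFractionA, pairs); empty (and flagged via
#'   `nMatched = 0`) when nothing matches.
#' @export
interregionDelays <- function(eventsA, eventsB, matchWindowS = 1.0) {
  oA <- onsets(eventsA); oB <- onsets(eventsB)
  if (!length(oA) || !length(oB)) stop("both event lists must be non-empty")
  cand <- expand.grid(i = seq_along(oA), j = seq_along(oB))
  cand$delta <- oB[cand$j] - oA[cand$i]
  cand <- cand[abs(cand$delta) <= matchWindowS, , drop = FALSE]
  cand <- cand[order(abs(cand$delta)), , drop = FALSE]
  usedA <- logical(length(oA)); usedB <- logical(length(oB))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!usedA[i] && !usedB[j]) { keep[k] <- TRUE; usedA[i] <- TRUE; usedB[j] <- TRUE }
  }
  pairs <- cand[keep, , drop = FALSE]
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  delays <- pairs$delta
  list(delaysS = delays,
       leaderFractionA = if (length(delays)) mean(delays > 0) else NA_real_,
       pairs = data.frame(onsetA = oA[pairs$i], onsetB = oB[pairs$j],
                          delayS = delays),
       nMatched = length(delays))
}
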