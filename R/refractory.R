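#' Time since the last spontaneous wave, per stimulus
#'
#' @param stimuli a [StimulusTrain-class] or sorted numeric onsets (s).
#' @param spontaneousOnsets sorted spontaneous wave onset times (s).
#' @return numeric, one interval (s) per stimulus; NA (excluded, flagged via
#'   the NA itself) when no onset precedes the stimulus.
#' @examples
#' timeSinceLast(c(7.2, 9.4), c(5, 9))   # 2.2, 0.4
#' @export
timeSinceLast <- function(stimuli, spontaneousOnsets) {
  stimOn <- if (is(stimuli, "StimulusTrain")) onsets(stimuli) else stimuli
  if (is.unsorted(stimOn) || is.unsorted(spontaneousOnsets))
    stop("inputs must be sorted")
  idx <- findInterval(stimOn, spontaneousOnsets)
  out <- rep(NA_real_, length(stimOn))
  has <- idx >= 1L
  out[has] <- stimOn[has] - spontaneousOnsets[idx[has]]
  ## a stimulus exactly at an onset has interval 0 from that onset
  out
}

#' Estimate the slow-wave refractory period from binned success rates
#'
#' Intervals (time since the last spontaneous wave at each stimulus) are
#' binned into contiguous `binS`-wide bins from 0; the refractory period is
#' the lower edge of the first bin whose success rate strictly exceeds
#' `criterion`. Bins with no stimuli are skipped (never treated as passing);
#' stimuli with NA intervals are excluded.
#'
#' @param intervals time since last spontaneous wave per stimulus (s).
#' @param successFlags logical: a wave followed the stimulus within the
#'   success window.
#' @param binS bin width (s), default 0.5.
#' @param criterion success-rate criterion, default 0.90 (strict >).
#' @param successWindowS success window recorded with the estimate (s).
#' @return a [RefractoryEstimate-class]; `tauS` is NA (with a warning) when
#'   no bin passes.
#' @examples
#' ## bins starting 0, 0.5, ..., 2.0 with rates 0.2, 0.5, 0.8, 0.95, 0.97
#' iv <- rep(seq(0.25, 2.25, by = 0.5), each = 100)
#' fl <- unlist(lapply(c(20, 50, 80, 95, 97),
#'                     function(k) rep(c(TRUE, FALSE), c(k, 100 - k))))
#' estimateRefractoryPeriod(iv, fl)  # tau_r = 1.5 s (0.95 > 0.90)
#' @export
estimateRefractoryPeriod <- function(intervals, successFlags, binS = 0.5,
                                     criterion = 0.90, successWindowS = 0.5) {
  if (length(intervals) != length(successFlags))
    stop("intervals and successFlags must be aligned")
  ok <- !is.na(intervals)
  intervals <- intervals[ok]; successFlags <- successFlags[ok]
  if (!length(intervals)) stop("no usable stimuli")
  nBins <- ceiling(max(intervals) / binS + 1e-9)
  nBins <- max(nBins, 1L)
  edges <- seq(0, nBins * binS, by = binS)
  binIdx <- pmin(floor(intervals / binS) + 1L, nBins)
  count <- tabulate(binIdx, nBins)
  succ <- vapply(seq_len(nBins), function(b) sum(successFlags[binIdx == b]),
                 numeric(1))
  rate <- ifelse(count > 0, succ / count, NA_real_)
  pass <- which(!is.na(rate) & rate > criterion)
  tau <- if (length(pass)) edges[pass[1]] else NA_real_
  if (is.na(tau)) warning("no bin exceeds the success criterion")
  new("RefractoryEstimate", binEdges = edges, count = as.integer(count),
      successRate = rate, tauS = tau, criterion = criterion,
      successWindowS = successWindowS)
}

#' Success flags from wave onsets
#'
#' Convenience helper: a stimulus succeeds when any wave onset falls within
#' `(stimulus, stimulus + successWindowS]`.
#'
#' @param stimuli a [StimulusTrain-class] or numeric onsets (s).
#' @param waveOnsets sorted wave onset times (s), evoked and spontaneous.
#' @param successWindowS success window (s), default 0.5.
#' @return logical per stimulus.
#' @export
successWithin <- function(stimuli, waveOnsets, successWindowS = 0.5) {
  stimOn <- if (is(stimuli, "StimulusTrain")) onsets(stimuli) else stimuli
  vapply(stimOn, function(s)
    any(waveOnsets > s & waveOnsets <= s + successWindowS), logical(1))
}

#' Latency vs interval table for refractory scatter analysis
#'
#' Joins, per stimulus, the time since the last spontaneous wave with the
#' latency to the next wave, flags stimuli inside the refractory period, and
#' summarizes the latency SD inside vs outside it.
#'
#' @param stimuli a [StimulusTrain-class] or numeric onsets (s).
#' @param spontaneousOnsets sorted spontaneous onsets (s).
#' @param evokedLatenciesS latency per stimulus (s), NA for failures; must
#'   align with the stimuli.
#' @param refractoryS refractory period used for flagging (s), default 2.
#' @return list(table = data.frame(stimulusS, intervalS, latencyS,
#'   refractory), sdInsideS, sdOutsideS).
#' @export
latencyIntervalTable <- function(stimuli, spontaneousOnsets, evokedLatenciesS,
                                 refractoryS = 2.0) {
  stimOn <- if (is(stimuli, "StimulusTrain")) onsets(stimuli) else stimuli
  if (length(stimOn) != length(evokedLatenciesS))
    stop("latency entries must align with the stimuli")
  if (!length(stimOn))
    return(list(table = data.frame(stimulusS = numeric(), intervalS = numeric(),
                                   latencyS = numeric(), refractory = logical()),
                sdInsideS = NA_real_, sdOutsideS = NA_real_))
  iv <- timeSinceLast(stimOn, spontaneousOnsets)
  refr <- !is.na(iv) & iv < refractoryS
  tab <- data.frame(stimulusS = stimOn, intervalS = iv,
                    latencyS = evokedLatenciesS, refractory = refr)
  sdIn <- stats::sd(tab$latencyS[tab$refractory], na.rm = TRUE)
  sdOut <- stats::sd(tab$latencyS[!tab$refractory], na.rm = TRUE)
  list(table = tab, sdInsideS = sdIn, sdOutsideS = sdOut)
}
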