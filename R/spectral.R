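## package-local cache for DPSS taper matrices
.dpssCache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequence (DPSS) tapers
#'
#' Computed as eigenvectors of the standard symmetric tridiagonal matrix
#' whose top eigenvectors are the Slepian sequences (diagonal
#' `((n-1-2t)/2)^2 cos(2 pi W)`, off-diagonal `t (n - t) / 2`, with
#' `W = nw / n`). Tapers are unit-energy and ordered by decreasing spectral
#' concentration; the sign convention makes the symmetric tapers' mean
#' positive and the antisymmetric tapers' initial slope positive.
#'
#' @param n taper length (samples).
#' @param nw time-bandwidth product.
#' @param k number of tapers; a warning is issued beyond `2 nw - 1`, where
#'   concentration degrades.
#' @return n x k matrix of tapers.
#' @export
dpssTapers <- function(n, nw, k) {
  if (k < 1) stop("k must be >= 1")
  if (k > 2 * nw - 1)
    warning("k > 2*nw - 1: highest-order tapers are poorly concentrated")
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.dpssCache[[key]])) return(.dpssCache[[key]])
  w <- nw / n
  tIdx <- 0:(n - 1)
  diagv <- ((n - 1 - 2 * tIdx) / 2)^2 * cos(2 * pi * w)
  offv <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  m <- matrix(0, n, n)
  diag(m) <- diagv
  m[cbind(1:(n - 1), 2:n)] <- offv
  m[cbind(2:n, 1:(n - 1))] <- offv
  eg <- eigen(m, symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    if (j %% 2L == 1L) {                   # symmetric taper: positive mean
      if (sum(v[, j]) < 0) v[, j] <- -v[, j]
    } else {                               # antisymmetric: positive lead
      if (sum(v[seq_len(n %/% 2), j]) < 0) v[, j] <- -v[, j]
    }
  }
  .dpssCache[[key]] <- v
  v
}

#' Multitaper spectrogram
#'
#' Sliding-window spectral estimate: per window the signal is demeaned,
#' multiplied by each DPSS taper, and the taper periodograms are averaged.
#' Power is one-sided density (units^2/Hz) so that the integral over
#' frequency approximates the signal variance.
#'
#' @param x numeric signal (or a [SampledTrace-class], in which case `fs` is
#'   taken from it).
#' @param fs sampling rate (Hz).
#' @param windowS,stepS moving-window size and step (s), defaults 0.4/0.2.
#' @param tw time-bandwidth product, default 4.
#' @param k number of tapers, default 9.
#' @param fpass numeric(2) frequency band to keep (Hz), default c(0, 40).
#' @return a [Spectrogram-class].
#' @export
multitaperSpectrogram <- function(x, fs = NULL, windowS = 0.4, stepS = 0.2,
                                  tw = 4, k = 9, fpass = c(0, 40)) {
  if (is(x, "SampledTrace")) { fs <- fsHz(x); x <- samples(x) }
  if (is.null(fs)) stop("fs is required for plain numeric input")
  n <- round(windowS * fs)
  if (n < 16) stop("window too short: need at least 16 samples")
  if (length(x) < n) stop("signal shorter than one window")
  tapers <- dpssTapers(n, tw, k)
  stepN <- max(1L, round(stepS * fs))
  starts <- seq(1L, length(x) - n + 1L, by = stepN)
  nfft <- 2^ceiling(log2(n))
  freqs <- (0:(nfft %/% 2)) * fs / nfft
  keep <- which(freqs >= fpass[1] & freqs <= fpass[2])
  segs <- vapply(starts, function(i) x[i:(i + n - 1L)], numeric(n))
  segs <- sweep(segs, 2, colMeans(segs))
  pow <- matrix(0, length(keep), length(starts))
  for (j in seq_len(k)) {
    tap <- segs * tapers[, j]
    tap <- rbind(tap, matrix(0, nfft - n, ncol(tap)))
    ft <- stats::mvfft(tap)
    pow <- pow + Mod(ft[keep, , drop = FALSE])^2
  }
  pow <- pow / k / fs
  ## one-sided density: double everything except DC and Nyquist
  dbl <- freqs[keep] > 0 & freqs[keep] < fs / 2
  pow[dbl, ] <- 2 * pow[dbl, ]
  new("Spectrogram", timeS = (starts - 1L) / fs + windowS / 2,
      freqHz = freqs[keep], power = t(pow),
      params = list(windowS = windowS, stepS = stepS, tw = tw, k = k,
                    fpass = fpass))
}

#' Brick-wall FFT band-pass filter
#'
#' Zero-phase band limiting by zeroing FFT coefficients outside `[loHz,
#' hiHz]`. Used for band-limited power (the pre/post windows of the
#' fold-change quantification are too short for stable IIR filtering at a
#' 0.5-Hz edge).
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param loHz,hiHz band edges (Hz); `loHz <= 0` keeps DC.
#' @return the band-limited signal.
#' @export
fftBandpass <- function(x, fs, loHz, hiHz) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  mask <- f >= loHz & f <= hiHz
  if (loHz <= 0) mask[1] <- TRUE
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

#' Band-limited log fold change of the stimulus response
#'
#' Segments around each stimulus are averaged first (stimulus-triggered
#' average of the raw signal), the average is band-limited, and the fold
#' change is the mean band-limited power in the post-stimulus window divided
#' by the mean power in the pre-stimulus window; the log (default base 10) is
#' reported.
#'
#' @param x numeric signal or [SampledTrace-class].
#' @param fs sampling rate (Hz) for numeric input.
#' @param stimuli a [StimulusTrain-class] or numeric onsets (s).
#' @param band numeric(2) frequency band (Hz); canonical bands are
#'   sub-gamma 0.5-35, gamma 35-200 and total 0.5-200.
#' @param postWindow,preWindow response and baseline windows relative to the
#'   stimulus (s); defaults c(0, 1.5) and c(-0.3, -0.1).
#' @param logBase base of the logarithm, default 10.
#' @param minStimuli minimum number of usable stimuli (default 10, with a
#'   warning below it; fewer than 2 is an error).
#' @return list(logFC, foldChange, band, nUsed).
#' @export
logFoldChange <- function(x, fs = NULL, stimuli, band = c(0.5, 35),
                          postWindow = c(0, 1.5), preWindow = c(-0.3, -0.1),
                          logBase = 10, minStimuli = 10) {
  if (is(x, "SampledTrace")) { fs <- fsHz(x); x <- samples(x) }
  if (is.null(fs)) stop("fs is required for plain numeric input")
  stimOn <- if (is(stimuli, "StimulusTrain")) onsets(stimuli) else stimuli
  pad <- 0.5
  lo <- min(preWindow[1], postWindow[1]) - pad
  hi <- max(preWindow[2], postWindow[2]) + pad
  nSeg <- round((hi - lo) * fs)
  segs <- list()
  for (s in stimOn) {
    i0 <- floor((s + lo) * fs) + 1L
    i1 <- i0 + nSeg - 1L
    if (i0 < 1L || i1 > length(x)) next
    segs[[length(segs) + 1L]] <- x[i0:i1]
  }
  nUsed <- length(segs)
  if (nUsed < 2) stop("need at least 2 stimuli with full windows in-bounds")
  if (nUsed < minStimuli)
    warning("fewer than ", minStimuli, " usable stimuli")
  avg <- Reduce(`+`, segs) / nUsed
  avg <- avg - mean(avg)
  bl <- fftBandpass(avg, fs, band[1], band[2])
  tRel <- lo + (seq_along(bl) - 1L) / fs
  prePow <- mean(bl[tRel >= preWindow[1] & tRel < preWindow[2]]^2)
  postPow <- mean(bl[tRel >= postWindow[1] & tRel < postWindow[2]]^2)
  if (!is.finite(prePow) || prePow <= 0)
    stop("undefined fold change: zero pre-stimulus power")
  fc <- postPow / prePow
  list(logFC = log(fc, base = logBase), foldChange = fc, band = band,
       nUsed = nUsed)
}

#' Detect slow-wave onsets from the power of an LFP signal
#'
#' The signal is converted to power over time (squared samples smoothed over
#' `smoothS`); onsets are upward crossings of `mean + kSd * SD` of the power
#' trace, with crossings closer than `mergeS` merged. The threshold is
#' relative, so the result is invariant to amplitude scaling.
#'
#' @param x numeric signal or [SampledTrace-class].
#' @param fs sampling rate (Hz) for numeric input.
#' @param kSd threshold in power-trace SDs, default 4.
#' @param smoothS smoothing window for the power trace (s), default 0.1.
#' @param mergeS minimum separation between onsets (s), default 0.5.
#' @param minDurationS recordings shorter than this are rejected (s).
#' @return numeric onset times (s); zero-length with attribute
#'   `flag = "no-onsets"` for constant input.
#' @export
detectSwOnsetsFromPower <- function(x, fs = NULL, kSd = 4, smoothS = 0.1,
                                    mergeS = 0.5, minDurationS = 10) {
  if (is(x, "SampledTrace")) { fs <- fsHz(x); x <- samples(x) }
  if (is.null(fs)) stop("fs is required for plain numeric input")
  if (length(x) / fs < minDurationS)
    stop(sprintf("recording must be at least %.0f s for stable statistics",
                 minDurationS))
  wN <- max(1L, round(smoothS * fs))
  p <- as.numeric(stats::filter(x^2, rep(1 / wN, wN), sides = 2))
  ## replicate the first/last full window into the filter edges
  ok <- which(!is.na(p))
  p[seq_len(ok[1] - 1)] <- p[ok[1]]
  if (ok[length(ok)] < length(p))
    p[(ok[length(ok)] + 1):length(p)] <- p[ok[length(ok)]]
  m <- mean(p); s <- stats::sd(p)
  if (!is.finite(s) || s == 0) {
    out <- numeric()
    attr(out, "flag") <- "no-onsets"
    return(out)
  }
  thr <- m + kSd * s
  up <- which(p[-1] > thr & p[-length(p)] <= thr) + 1L
  if (length(up) > 1) {
    ## merge chains: keep a crossing only when >= mergeS after the last kept
    sel <- logical(length(up))
    last <- -Inf
    for (i in seq_along(up)) {
      if ((up[i] - last) / fs >= mergeS) { sel[i] <- TRUE; last <- up[i] }
    }
    up <- up[sel]
  }
  (up - 1L) / fs
}

#' Label stimuli delivered in the refractory period
#'
#' A stimulus is refractory when the most recent spontaneous onset occurred
#' strictly within `windowS` before it; stimuli with no prior onset are
#' non-refractory.
#'
#' @param stimuli a [StimulusTrain-class] or sorted numeric onsets (s).
#' @param spontaneousOnsets sorted spontaneous onset times (s).
#' @param windowS refractory window (s), default 2.
#' @return logical, one entry per stimulus.
#' @export
labelRefractory <- function(stimuli, spontaneousOnsets, windowS = 2.0) {
  stimOn <- if (is(stimuli, "StimulusTrain")) onsets(stimuli) else stimuli
  tsl <- timeSinceLast(stimOn, spontaneousOnsets)
  !is.na(tsl) & tsl < windowS
}
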