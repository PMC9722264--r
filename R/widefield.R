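## frame index of the last frame acquired strictly before a time point
frameBefore <- function(movie, timeS) {
  ft <- frameTimesS(movie)
  idx <- max(which(ft < timeS))
  if (!is.finite(idx) || idx < 1L) stop("no frame precedes the stimulus onset")
  idx
}

#' Convert a raw movie to percent df/f against a pre-stimulus reference frame
#'
#' Per pixel, `df/f_t = 100 * (F_t - F0) / F0` with `F0` the frame
#' immediately preceding the stimulus onset. Pixels with `F0 <= 0` are masked
#' (NA) with a warning.
#'
#' @param movie a raw [CalciumMovie-class].
#' @param stimulusOnsetS stimulus time (s); must fall after the first frame.
#' @return a [CalciumMovie-class] in percent df/f, time origin unchanged.
#' @export
dffMovie <- function(movie, stimulusOnsetS) {
  stopifnot(is(movie, "CalciumMovie"), movie@units == "raw")
  i0 <- frameBefore(movie, stimulusOnsetS)
  f <- frames(movie)
  f0 <- f[i0, , ]
  bad <- !is.finite(f0) | f0 <= 0
  if (any(bad)) {
    warning(sum(bad), " pixels with nonpositive reference masked")
    f0[bad] <- NA_real_
  }
  d <- 100 * sweep(f, c(2, 3), f0, function(a, b) (a - b) / b)
  initialize(movie, frames = d, units = "dff_pct")
}

#' Stimulus-triggered average df/f stack
#'
#' For every stimulus with a full window in-bounds, a df/f segment referenced
#' to the frame before that stimulus is extracted and aligned at onset; the
#' frame-wise mean across stimuli is returned as a movie whose time origin
#' (`t0S`) is relative to the stimulus onset.
#'
#' @param movie a raw [CalciumMovie-class].
#' @param stimuli a [StimulusTrain-class] or numeric onset vector (s).
#' @param windowS numeric(2), window around the stimulus (s),
#'   default c(-1, 3).
#' @return list(stack = [CalciumMovie-class] of averaged df/f with
#'   stimulus-relative frame times, nUsed = number of stimuli averaged).
#' @export
stimulusTriggeredAverage <- function(movie, stimuli, windowS = c(-1, 3)) {
  stopifnot(is(movie, "CalciumMovie"))
  stimOn <- if (is(stimuli, "StimulusTrain")) onsets(stimuli) else stimuli
  fr <- frameRateHz(movie)
  ft <- frameTimesS(movie)
  nT <- length(ft)
  kPre <- ceiling(-windowS[1] * fr)
  kPost <- ceiling(windowS[2] * fr)
  segs <- list()
  offsets <- numeric()
  for (s in stimOn) {
    if (s <= ft[1] || s + windowS[1] < ft[1] - 1e-9) next
    i0 <- max(which(ft < s))
    if (i0 - kPre < 1L || i0 + kPost > nT) next
    f0 <- frames(movie)[i0, , ]
    if (any(!is.finite(f0)) || any(f0 <= 0)) next
    seg <- frames(movie)[(i0 - kPre):(i0 + kPost), , , drop = FALSE]
    segs[[length(segs) + 1L]] <- 100 * sweep(seg, c(2, 3), f0,
                                             function(a, b) (a - b) / b)
    offsets <- c(offsets, ft[i0] - s)
  }
  if (!length(segs)) stop("no stimulus with a full window in-bounds")
  avg <- Reduce(`+`, segs) / length(segs)
  t0 <- mean(offsets) - kPre / fr
  stack <- new("CalciumMovie", frames = avg, frameRateHz = fr, t0S = t0,
               geometry = geometry(movie), units = "dff_pct",
               aligned = movie@aligned)
  list(stack = stack, nUsed = length(segs))
}

## per-pixel pre-stimulus mean and SD from frames with t in [-prestim, 0)
prestimStats <- function(stack, prestimWindowS) {
  ft <- frameTimesS(stack)
  pre <- which(ft < 0 & ft >= -prestimWindowS)
  if (length(pre) < 3) stop("prestimulus window must contain at least 3 frames")
  f <- frames(stack)[pre, , , drop = FALSE]
  mu <- apply(f, c(2, 3), mean)
  sd <- apply(f, c(2, 3), stats::sd)
  list(mean = mu, sd = sd)
}

#' Pixel-wise response-onset latency map
#'
#' Per pixel, the onset is the first post-stimulus frame in which the
#' averaged df/f exceeds `prestim mean + kSd * prestim SD`. With frame
#' intervals comparable to the calcium rise time, the crossing frame alone
#' quantizes latencies too coarsely for gradient analysis, so the crossing
#' time is refined to sub-frame precision by interpolating the pixel time
#' course around the crossing (cubic spline by default, falling back to
#' linear interpolation where the spline has no bracketed root). Pixels that
#' never cross, or with zero pre-stimulus variance, are missing (NA).
#'
#' @param stack stimulus-triggered average [CalciumMovie-class] (df/f, with
#'   stimulus-relative frame times, i.e. `t0S < 0`).
#' @param prestimWindowS pre-stimulus window used for the pixel statistics
#'   (s), default 1.
#' @param kSd threshold in pre-stimulus SDs, default 3.5.
#' @param interpolate "spline" (default), "linear", or "none" (crossing-frame
#'   time).
#' @param sdFloorPct absolute floor (percent df/f) applied to the per-pixel
#'   pre-stimulus SD. The default 0 masks zero-variance pixels; a positive
#'   floor makes noise-free synthetic stacks analysable and keeps the
#'   threshold on the rising phase of the response, where the interpolated
#'   crossing carries sub-frame timing information.
#' @return a [LatencyMap-class].
#' @export
onsetLatencyMap <- function(stack, prestimWindowS = 1, kSd = 3.5,
                            interpolate = c("spline", "linear", "none"),
                            sdFloorPct = 0) {
  stopifnot(is(stack, "CalciumMovie"))
  interpolate <- match.arg(interpolate)
  ps <- prestimStats(stack, prestimWindowS)
  ps$sd <- pmax(ps$sd, sdFloorPct)
  ft <- frameTimesS(stack)
  post <- which(ft >= 0)
  if (!length(post)) stop("stack contains no post-stimulus frames")
  f <- frames(stack)
  hw <- dim(f)[2:3]
  lat <- matrix(NA_real_, hw[1], hw[2])
  thr <- ps$mean + kSd * ps$sd
  degenerate <- !is.finite(ps$sd) | ps$sd == 0
  nT <- length(ft)
  for (r in seq_len(hw[1])) {
    for (cc in seq_len(hw[2])) {
      if (degenerate[r, cc]) next
      y <- f[, r, cc]
      th <- thr[r, cc]
      ## first genuine upward crossing after the stimulus; pixels already
      ## above threshold at stimulus time have no onset and stay missing
      j <- which(y[post] > th & y[pmax(post - 1L, 1L)] <= th)
      if (!length(j)) next
      jj <- post[j[1]]
      tj <- ft[jj]
      if (interpolate != "none" && jj > 1L &&
          is.finite(y[jj - 1L]) && y[jj - 1L] <= th && y[jj] > y[jj - 1L]) {
        tLin <- ft[jj - 1L] + (ft[jj] - ft[jj - 1L]) *
          (th - y[jj - 1L]) / (y[jj] - y[jj - 1L])
        tj <- tLin
        if (interpolate == "spline" && jj > 2L) {
          idx <- max(1L, jj - 3L):min(nT, jj + 2L)
          sf <- stats::splinefun(ft[idx], y[idx], method = "natural")
          tj <- tryCatch(
            stats::uniroot(function(t) sf(t) - th, c(ft[jj - 1L], ft[jj]))$root,
            error = function(e) tLin)
        }
      }
      lat[r, cc] <- max(tj, 0)
    }
  }
  new("LatencyMap", latencyS = lat, geometry = geometry(stack))
}

#' Response area from a triggered-average stack
#'
#' A pixel counts as activated in a frame when its df/f exceeds its
#' pre-stimulus mean + `kSd` SD. The response area is the maximum
#' simultaneous number of activated pixels over the frames inside `windowS`
#' (default 1-2 s post-stimulus) times the pixel area
#' (`mode = "simultaneous"`), or the number of pixels activated in any frame
#' of the window (`mode = "cumulative"`).
#'
#' @param x stimulus-triggered average [CalciumMovie-class].
#' @param windowS numeric(2) post-stimulus window (s), default c(1, 2).
#' @param kSd threshold in pre-stimulus SDs, default 3.5.
#' @param prestimWindowS pre-stimulus statistics window (s), default 1.
#' @param mode "simultaneous" (default) or "cumulative".
#' @param sdFloorPct floor (percent df/f) on the per-pixel pre-stimulus SD;
#'   see [onsetLatencyMap()].
#' @param ... unused.
#' @return area in mm^2 (zero allowed).
#' @name responseArea
NULL

#' @rdname responseArea
#' @export
setMethod("responseArea", "CalciumMovie",
  function(x, windowS = c(1, 2), kSd = 3.5, prestimWindowS = 1,
           mode = c("simultaneous", "cumulative"), sdFloorPct = 0, ...) {
    mode <- match.arg(mode)
    ps <- prestimStats(x, prestimWindowS)
    ps$sd <- pmax(ps$sd, sdFloorPct)
    ft <- frameTimesS(x)
    inWin <- which(ft >= windowS[1] & ft <= windowS[2])
    if (!length(inWin)) stop("window lies outside the stack")
    thr <- ps$mean + kSd * ps$sd
    thr[!is.finite(ps$sd) | ps$sd == 0] <- Inf
    f <- frames(x)
    active <- vapply(inWin, function(i) {
      a <- f[i, , ] > thr
      a[!is.finite(a)] <- FALSE
      a
    }, matrix(TRUE, dim(f)[2], dim(f)[3]))
    nPix <- if (mode == "simultaneous") {
      max(apply(active, 3, sum))
    } else sum(apply(active, c(1, 2), any))
    nPix * geometry(x)@pixelPitchMm^2
  })

#' @rdname responseArea
#' @export
setMethod("responseArea", "LatencyMap",
  function(x, windowS = c(1, 2), ...) {
    lat <- latencies(x)
    sum(!is.na(lat) & lat >= windowS[1] & lat <= windowS[2]) *
      geometry(x)@pixelPitchMm^2
  })

## median filter ignoring NA; window w x w, requires >= minValid finite values
medianSmooth <- function(m, w = 3, minValid = 3) {
  if (w <= 1) return(m)
  h <- nrow(m); wd <- ncol(m)
  half <- (w - 1) %/% 2
  out <- m
  for (r in seq_len(h)) {
    r0 <- max(1, r - half); r1 <- min(h, r + half)
    for (cc in seq_len(wd)) {
      c0 <- max(1, cc - half); c1 <- min(wd, cc + half)
      v <- m[r0:r1, c0:c1]
      v <- v[is.finite(v)]
      out[r, cc] <- if (length(v) >= minValid) stats::median(v) else NA_real_
    }
  }
  out
}

## local least-squares plane fit of the latency map: gradient (s/mm) in the
## (anterior, lateral) frame at every pixel with enough finite neighbours
planeFitGradient <- function(lat, pitch, fitPx, minValid) {
  h <- nrow(lat); w <- ncol(lat)
  gAp <- matrix(NA_real_, h, w)
  gMl <- matrix(NA_real_, h, w)
  for (r in seq_len(h)) {
    r0 <- max(1L, r - fitPx); r1 <- min(h, r + fitPx)
    for (cc in seq_len(w)) {
      if (!is.finite(lat[r, cc])) next
      c0 <- max(1L, cc - fitPx); c1 <- min(w, cc + fitPx)
      sub <- lat[r0:r1, c0:c1]
      ok <- is.finite(sub)
      if (sum(ok) < minValid) next
      rows <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
      cols <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
      x <- cbind(1, rows[ok] * pitch, cols[ok] * pitch)
      cf <- tryCatch(qr.coef(qr(x), sub[ok]), error = function(e) rep(NA_real_, 3))
      ## rows run anterior -> posterior: +row = -anterior
      gAp[r, cc] <- -cf[2]
      gMl[r, cc] <- cf[3]
    }
  }
  list(gAp = gAp, gMl = gMl)
}

#' Propagation velocity field from a latency map
#'
#' The latency map is median-smoothed (`smoothPx` x `smoothPx`, robust to
#' isolated outliers), then the spatial gradient `g = grad(t)` (s/mm) is
#' estimated at every pixel by a least-squares plane fit over a local
#' `(2 fitPx + 1)`-pixel window. The fit window is deliberately larger than
#' the distance the wave travels per frame (speed / frame rate, ~1.5 mm at
#' 30 mm/s and 20 Hz): latencies carry frame-quantization structure on that
#' scale, and simple nearest-neighbour differences are dominated by it.
#' Speed is `1 / |g|`; the direction is the direction of increasing latency
#' (early to late, i.e. the propagation direction) in the package convention
#' (0 = anterior, +pi/2 = lateral). Pixels with gradient magnitude below
#' `1 / maxSpeedMmS` (near-simultaneous activation, no direction
#' information), with too few finite neighbours, or with latency below
#' `clipS` (pixels already active at the stimulus) are invalid.
#'
#' @param latencyMap a [LatencyMap-class].
#' @param smoothPx median-filter width in pixels (odd; 0 or 1 disables).
#' @param fitPx plane-fit half-width in pixels, default 10.
#' @param maxSpeedMmS speed ceiling (mm/s), default 1000.
#' @param minValid minimum finite pixels in a fit window, default 20.
#' @param clipS latencies at or below this are treated as pre-activated and
#'   excluded (s): a pixel crossing threshold within a fraction of a frame of
#'   the stimulus was typically rising already at stimulus time and carries
#'   no wavefront timing. Default 0.025 s (half a frame at 20 Hz).
#' @return a [VelocityField-class].
#' @export
velocityField <- function(latencyMap, smoothPx = 3, fitPx = 10,
                          maxSpeedMmS = 1000, minValid = 20, clipS = 0.025) {
  stopifnot(is(latencyMap, "LatencyMap"))
  lat <- latencies(latencyMap)
  if (sum(is.finite(lat)) < 9) stop("need at least 3 x 3 valid pixels")
  lat <- medianSmooth(lat, smoothPx)
  pitch <- geometry(latencyMap)@pixelPitchMm
  lat[lat <= clipS] <- NA_real_
  g <- planeFitGradient(lat, pitch, fitPx, minValid)
  mag <- sqrt(g$gAp^2 + g$gMl^2)
  valid <- is.finite(mag) & mag > 1 / maxSpeedMmS
  h <- nrow(lat); w <- ncol(lat)
  speed <- matrix(NA_real_, h, w)
  dir <- matrix(NA_real_, h, w)
  speed[valid] <- 1 / mag[valid]
  dir[valid] <- wrapAngle(atan2(g$gMl[valid], g$gAp[valid]))
  if (!any(valid)) stop("degenerate latency map: no valid velocity pixels")
  new("VelocityField", speedMmS = speed, directionRad = dir, valid = valid,
      geometry = geometry(latencyMap))
}

#' Mean velocity vector of a field
#'
#' Cartesian average of the per-pixel velocity vectors, converted back to
#' speed and direction.
#'
#' @param field a [VelocityField-class].
#' @return named numeric(2): `speedMmS`, `directionRad`.
#' @export
meanVelocityVector <- function(field) {
  stopifnot(is(field, "VelocityField"))
  v <- validMask(field)
  if (!any(v)) stop("degenerate field: no valid pixels")
  sp <- speeds(field)[v]; th <- directions(field)[v]
  vx <- mean(sp * cos(th)); vy <- mean(sp * sin(th))
  c(speedMmS = sqrt(vx^2 + vy^2), directionRad = atan2(vy, vx))
}

#' Activation-probability distribution of a movie
#'
#' The field-of-view mean trace is normalized to [0, 1] activation using its
#' 1st/99th percentiles (robust min-max), clipped, and histogrammed into
#' `nBins` equal bins as probability mass.
#'
#' @param movie a [CalciumMovie-class] (>= `minDurationS` of data).
#' @param nBins number of bins, default 20.
#' @param probs normalization percentiles, default c(0.01, 0.99).
#' @param minDurationS minimum movie duration (s), default 10.
#' @param id identifier stored with the histogram.
#' @return an [ActivationHistogram-class].
#' @export
activationDistribution <- function(movie, nBins = 20, probs = c(0.01, 0.99),
                                   minDurationS = 10, id = "recording") {
  stopifnot(is(movie, "CalciumMovie"))
  nT <- dim(frames(movie))[1]
  if (nT / frameRateHz(movie) < minDurationS)
    stop(sprintf("movie must span at least %.0f s", minDurationS))
  tr <- apply(frames(movie), 1, mean, na.rm = TRUE)
  q <- stats::quantile(tr, probs, names = FALSE)
  if (q[2] <= q[1]) stop("degenerate normalization: constant mean trace")
  act <- pmin(pmax((tr - q[1]) / (q[2] - q[1]), 0), 1)
  edges <- seq(0, 1, length.out = nBins + 1)
  ## bins are [a, b) with the top edge included in the last bin
  counts <- graphics::hist(act, breaks = edges, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  counts <- counts / sum(counts)
  new("ActivationHistogram", binEdges = edges, mass = counts, id = id)
}

#' Permutation comparison of activation histograms
#'
#' Per bin, the statistic is the difference of group means of bin mass; the
#' null is built by permuting the animal group labels. Two-sided p-values use
#' the add-one rule `p = (1 + #{|perm| >= |obs|}) / (nPerm + 1)` and are
#' Bonferroni-adjusted over bins.
#'
#' @param histsA,histsB lists of [ActivationHistogram-class] (>= 2 animals
#'   per group) with identical bin edges.
#' @param nPerm number of permutations, default 10000.
#' @param seed optional RNG seed.
#' @return data.frame(bin, lower, upper, meanA, meanB, diff, p, pAdj).
#' @export
compareDistributionsPermutation <- function(histsA, histsB, nPerm = 10000,
                                            seed = NULL) {
  if (length(histsA) < 2 || length(histsB) < 2)
    stop("need at least 2 animals per group")
  if (nPerm < 100) warning("fewer than 100 permutations is unreliable")
  if (!is.null(seed)) set.seed(seed)
  edges <- histsA[[1]]@binEdges
  mA <- do.call(rbind, lapply(histsA, function(h) h@mass))
  mB <- do.call(rbind, lapply(histsB, function(h) h@mass))
  if (ncol(mA) != ncol(mB)) stop("histograms must share bin edges")
  nA <- nrow(mA)
  all <- rbind(mA, mB)
  obs <- colMeans(mA) - colMeans(mB)
  exceed <- rep(0L, ncol(all))
  for (k in seq_len(nPerm)) {
    idx <- sample.int(nrow(all), nA)
    stat <- colMeans(all[idx, , drop = FALSE]) -
      colMeans(all[-idx, , drop = FALSE])
    exceed <- exceed + (abs(stat) >= abs(obs) - 1e-15)
  }
  p <- (1 + exceed) / (nPerm + 1)
  nBins <- ncol(all)
  data.frame(bin = seq_len(nBins), lower = edges[-length(edges)],
             upper = edges[-1], meanA = colMeans(mA), meanB = colMeans(mB),
             diff = obs, p = p, pAdj = pmin(p * nBins, 1))
}
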