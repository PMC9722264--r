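#' Generate a stimulus train
#'
#' Builds regularly spaced (optionally jittered) single-pulse stimuli, or a
#' block paradigm in which every block contains a pulse train at a fixed rate
#' (e.g. 4 s at 3 Hz, i.e. 12 pulses per block).
#'
#' @param modality "visual" or "somatosensory".
#' @param nStimuli number of stimuli (blocks when `trainSpec` is given).
#' @param isiS inter-stimulus (inter-block) interval in seconds; either a
#'   scalar for regular spacing or a length-2 range for uniform jitter.
#' @param trainSpec optional `list(rateHz =, durationS =)` block description.
#' @param tStart time of the first stimulus (s), default 0.
#' @param pulseMs pulse duration (ms), metadata.
#' @param amplitudeMa stimulation amplitude (mA), metadata.
#' @param seed optional RNG seed used when `isiS` is a jitter range.
#' @return A [StimulusTrain-class]. With a `trainSpec`, the onsets are the
#'   individual pulse times of every block.
#' @examples
#' generateStimulusTrain("somatosensory", nStimuli = 3, isiS = 10)
#' generateStimulusTrain("somatosensory", nStimuli = 1, isiS = 20,
#'                       trainSpec = list(rateHz = 3, durationS = 4))
#' @export
generateStimulusTrain <- function(modality = c("visual", "somatosensory"),
                                  nStimuli, isiS, trainSpec = NULL,
                                  tStart = 0, pulseMs = 10, amplitudeMa = 1,
                                  seed = NULL) {
  modality <- match.arg(modality)
  if (nStimuli < 1) stop("nStimuli must be >= 1")
  if (any(isiS <= 0)) stop("inter-stimulus interval must be positive")
  if (!is.null(trainSpec)) {
    if (is.null(trainSpec$rateHz) || is.null(trainSpec$durationS) ||
        trainSpec$rateHz <= 0 || trainSpec$durationS <= 0)
      stop("trainSpec needs positive rateHz and durationS")
  }
  if (length(isiS) == 2L) {
    if (!is.null(seed)) set.seed(seed)
    gaps <- stats::runif(nStimuli - 1L, isiS[1], isiS[2])
    starts <- tStart + c(0, cumsum(gaps))
    isiTxt <- sprintf("ISI jittered %.3g-%.3g s", isiS[1], isiS[2])
  } else {
    starts <- tStart + (seq_len(nStimuli) - 1L) * isiS
    isiTxt <- sprintf("ISI %.3g s", isiS)
  }
  if (is.null(trainSpec)) {
    onsets <- starts
  } else {
    nPulse <- floor(trainSpec$rateHz * trainSpec$durationS)
    pulseTimes <- (seq_len(nPulse) - 1L) / trainSpec$rateHz
    onsets <- as.vector(outer(pulseTimes, starts, `+`))
    onsets <- sort(onsets)
    isiTxt <- sprintf("%s, trains of %.3g s at %.3g Hz", isiTxt,
                      trainSpec$durationS, trainSpec$rateHz)
  }
  new("StimulusTrain", onsetsS = onsets, modality = modality,
      pulseMs = pulseMs, amplitudeMa = amplitudeMa, isi = isiTxt)
}
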