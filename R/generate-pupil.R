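#' Closed-form event-related pupil dilation shape
#'
#' Unit-amplitude saturating-exponential dilation starting at cue onset:
#' \eqn{h(t) = (1 - e^{-t/\tau})} for t > 0, 0 before onset. Used by the
#' generator and available to parameter-recovery oracles.
#'
#' @param timesMs sample times (ms) relative to cue onset.
#' @param tauMs rise time constant (ms), default 500.
#' @return numeric vector of unit-amplitude response values.
#' @export
pupilResponseShape <- function(timesMs, tauMs = 500) {
  ifelse(timesMs > 0, 1 - exp(-timesMs / tauMs), 0)
}

#' Generate per-trial pupil traces for one subject
#'
#' Traces at 60 Hz spanning -500..+4000 ms around cue onset: a constant
#' tonic diameter, plus an event-related dilation of amplitude
#' \code{pupilGainMm * gradient(orientation) + pupilContextOffsetMm *
#' [aversive]}, plus white measurement noise. Blinks arrive as a Poisson
#' process at \code{blinkRateHz}; each masks a 150-400 ms gap as missing
#' samples. Deterministic given (params@seed, subjectId).
#'
#' @param schedule a TrialSchedule.
#' @param params a GenParams.
#' @param subjectId integer.
#' @param sfreq sampling rate, default 60 Hz.
#' @param windowMs trace window (ms), default c(-500, 4000).
#' @param tonicMm tonic pupil diameter (mm), default 3.5.
#' @return a \linkS4class{PupilTraceSet} (missing samples are NA).
#' @export
generatePupil <- function(schedule, params, subjectId, sfreq = 60,
                          windowMs = c(-500, 4000), tonicMm = 3.5) {
  rec <- scheduleRecords(schedule)
  if (!nrow(rec)) stop("schedule must be non-empty")
  nSamp <- as.integer(round((windowMs[2] - windowMs[1]) / 1000 * sfreq))
  times <- windowMs[1] + (seq_len(nSamp) - 1L) * 1000 / sfreq
  shape <- pupilResponseShape(times)
  nTr <- nrow(rec)
  withSeed(deriveSeed(params@seed, "pupil", subjectId), {
    grad <- orientationGradient(rec$orientation_deg, params@a2GradientWidthDeg)
    amp <- params@pupilGainMm * grad +
      params@pupilContextOffsetMm * (rec$context == "aversive")
    traces <- tonicMm + outer(amp, shape) +
      matrix(stats::rnorm(nTr * nSamp, 0, params@pupilNoiseSd), nTr, nSamp)
    miss <- matrix(FALSE, nTr, nSamp)
    if (params@blinkRateHz > 0) {
      durS <- (windowMs[2] - windowMs[1]) / 1000
      for (tr in seq_len(nTr)) {
        nBlink <- stats::rpois(1, params@blinkRateHz * durS)
        if (nBlink > 0) {
          starts <- stats::runif(nBlink, 0, durS) * 1000 + windowMs[1]
          lens <- stats::runif(nBlink, 150, 400)
          for (b in seq_len(nBlink)) {
            gap <- times >= starts[b] & times <= starts[b] + lens[b]
            miss[tr, gap] <- TRUE
          }
        }
      }
      # never blank an entire trial
      full <- rowSums(!miss) < 2L
      miss[full, ] <- FALSE
      traces[miss] <- NA_real_
    }
    labels <- data.frame(orientation_deg = rec$orientation_deg,
                         context = rec$context, phase = rec$phase)
    new("PupilTraceSet", traces = traces, missingMask = miss,
        timesMs = times, sfreq = sfreq, labels = labels)
  })
}
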