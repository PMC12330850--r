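#' Linearly interpolate missing pupil samples
#'
#' Gaps from blinks or tracking loss are filled by linear interpolation
#' between the flanking valid samples; leading/trailing gaps are filled by
#' nearest-valid extension. Trials without at least 2 valid samples are
#' flagged and excluded.
#'
#' @param traces a \linkS4class{PupilTraceSet}.
#' @return a PupilTraceSet without missing samples; dropped trials (if any)
#'   are recorded in the returned object's labels via attribute
#'   "droppedTrials".
#' @export
interpolateMissing <- function(traces) {
  tr <- traces@traces
  valid <- rowSums(!is.na(tr))
  drop <- which(valid < 2L)
  keep <- setdiff(seq_len(nrow(tr)), drop)
  tr <- tr[keep, , drop = FALSE]
  mm <- traces@missingMask[keep, , drop = FALSE]
  x <- traces@timesMs
  for (i in seq_len(nrow(tr))) {
    if (anyNA(tr[i, ])) {
      ok <- !is.na(tr[i, ])
      tr[i, ] <- stats::approx(x[ok], tr[i, ok], xout = x, rule = 2)$y
    }
  }
  out <- new("PupilTraceSet", traces = tr, missingMask = mm,
             timesMs = traces@timesMs, sfreq = traces@sfreq,
             labels = traces@labels[keep, , drop = FALSE])
  attr(out, "droppedTrials") <- drop
  out
}

#' Zero-phase low-pass filter for pupil traces
#'
#' @param traces a PupilTraceSet without missing samples.
#' @param cutoffHz cutoff, default 2 Hz.
#' @param order Butterworth order, default 2 (applied forward-backward).
#' @return a filtered PupilTraceSet.
#' @export
pupilLowpass <- function(traces, cutoffHz = 2, order = 2) {
  if (anyNA(traces@traces))
    stop("interpolate missing samples before filtering")
  bf <- signal::butter(order, cutoffHz / (traces@sfreq / 2), type = "low")
  tr <- t(filtfiltMat(bf$b, bf$a, t(traces@traces)))
  initialize(traces, traces = tr)
}

#' Subtract the pre-cue baseline mean per trial
#'
#' @param traces a PupilTraceSet.
#' @param baselineMs baseline window (ms), default c(-500, 0) (the 0 ms
#'   sample is excluded: the window is pre-stimulus).
#' @return a baseline-corrected PupilTraceSet.
#' @export
baselineCorrect <- function(traces, baselineMs = c(-500, 0)) {
  idx <- which(traces@timesMs >= baselineMs[1] - 1e-9 &
                 traces@timesMs < baselineMs[2] - 1e-9)
  if (!length(idx)) stop("baseline window outside the trace")
  base <- rowMeans(traces@traces[, idx, drop = FALSE])
  if (anyNA(base)) stop("baseline fully or partly missing; interpolate first")
  initialize(traces, traces = traces@traces - base)
}

#' Mean event-related pupil response per trial
#'
#' Arithmetic mean of the (baseline-corrected) samples within the response
#' window, the scalar entering the condition-level analysis.
#'
#' @param traces a baseline-corrected PupilTraceSet.
#' @param windowMs response window (ms), default c(500, 4000).
#' @return numeric vector, one mean change (mm) per trial.
#' @export
meanResponse <- function(traces, windowMs = c(500, 4000)) {
  idx <- which(traces@timesMs >= windowMs[1] - 1e-9 &
                 traces@timesMs <= windowMs[2] + 1e-9)
  if (!length(idx)) stop("response window outside the trace")
  rowMeans(traces@traces[, idx, drop = FALSE])
}

#' Full per-subject pupil pipeline
#'
#' interpolate -> 2 Hz low-pass -> baseline-correct -> window mean,
#' aggregated to condition means.
#'
#' @param traces a raw PupilTraceSet.
#' @param grouping condition label columns.
#' @return data.frame of condition means (columns: grouping..., response_mm,
#'   n_trials).
#' @export
pupilConditionMeans <- function(traces,
                                grouping = c("orientation_deg", "context")) {
  pp <- baselineCorrect(pupilLowpass(interpolateMissing(traces)))
  resp <- meanResponse(pp)
  lab <- pp@labels[, grouping, drop = FALSE]
  agg <- stats::aggregate(resp, lab, mean)
  names(agg)[ncol(agg)] <- "response_mm"
  cnt <- stats::aggregate(resp, lab, length)
  agg$n_trials <- cnt$x
  agg
}
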