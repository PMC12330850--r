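#' @import methods
NULL

CUE_ORIENTATIONS <- c(-45, 15, 25, 35, 45, 55, 65, 75)
CS_PLUS_DEG <- 45
WEIGHTED_ORIENTATIONS <- c(15, 25, 35, 45, 55, 65, 75)

#' SensorNet: electrode labels, unit-sphere positions and the occipital pool
#'
#' Container for a dense-array EEG sensor layout. Positions live on the unit
#' sphere (head-centred coordinates: x right, y anterior, z superior). The
#' occipital pool holds the eight sensors (Oz plus seven neighbours) over
#' which ssVEP signal-to-noise ratios are pooled for statistical analysis.
#'
#' @slot sensorIds character vector of electrode labels.
#' @slot positions numeric matrix (sensors x 3) of unit-norm coordinates.
#' @slot occipitalPool character vector of eight pool sensor labels.
#' @export
setClass("SensorNet",
  representation(sensorIds = "character",
                 positions = "matrix",
                 occipitalPool = "character"))

setValidity("SensorNet", function(object) {
  msg <- character()
  n <- length(object@sensorIds)
  if (anyDuplicated(object@sensorIds))
    msg <- c(msg, "sensor ids must be unique")
  if (!is.numeric(object@positions) || nrow(object@positions) != n ||
      ncol(object@positions) != 3)
    msg <- c(msg, "positions must be a numeric (sensors x 3) matrix")
  else {
    norms <- sqrt(rowSums(object@positions^2))
    if (any(abs(norms - 1) > 1e-9))
      msg <- c(msg, "all sensor positions must have unit norm (tol 1e-9)")
  }
  if (length(object@occipitalPool) != 8L)
    msg <- c(msg, "occipitalPool must have exactly 8 members")
  if (!all(object@occipitalPool %in% object@sensorIds))
    msg <- c(msg, "occipitalPool must be a subset of sensorIds")
  if (length(msg)) msg else TRUE
})

#' TrialSchedule: ordered trial records of a conditioning phase
#'
#' One row per cue presentation with the phase (acquisition or context),
#' block index, context (aversive/neutral, or none during acquisition),
#' Gabor orientation in degrees, onset relative to block start, cue duration,
#' the inter-stimulus interval that follows the cue, and whether the trial is
#' reinforced by the aversive unconditioned stimulus (CS+ = +45 deg, 100%
#' reinforcement).
#'
#' @slot records data.frame with columns phase, block_index, context,
#'   orientation_deg, onset_s, duration_s, isi_s, reinforced.
#' @export
setClass("TrialSchedule", representation(records = "data.frame"))

setValidity("TrialSchedule", function(object) {
  rec <- object@records
  need <- c("phase", "block_index", "context", "orientation_deg",
            "onset_s", "duration_s", "isi_s", "reinforced")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (!all(rec$phase %in% c("acquisition", "context")))
    msg <- c(msg, "phase must be 'acquisition' or 'context'")
  if (!all(rec$context %in% c("aversive", "neutral", "none")))
    msg <- c(msg, "context must be 'aversive', 'neutral' or 'none'")
  if (!all(rec$orientation_deg %in% CUE_ORIENTATIONS))
    msg <- c(msg, "orientation_deg outside the cue set")
  if (!all(rec$reinforced == (rec$orientation_deg == CS_PLUS_DEG)))
    msg <- c(msg, "reinforced must be true iff orientation is +45 (CS+)")
  if (length(msg)) msg else TRUE
})

#' GenParams: generative parameters of the synthetic cohort
#'
#' Houses every tunable of the synthetic-data generator: ssVEP amplitudes at
#' the fundamental (with its aversive-context increment) and second harmonic
#' (with a Gaussian generalization gradient over orientation distance from
#' CS+), the 1/f background-noise model, between-subject amplitude
#' variability, and the rating and pupil response models.
#'
#' @slot nSubjects integer, cohort size.
#' @slot f0Hz driving (flicker) frequency in Hz.
#' @slot a1Base,a1ContextOffset fundamental amplitude (uV) and its aversive
#'   increment.
#' @slot a2Base,a2GradientPeak,a2GradientWidthDeg harmonic amplitude (uV),
#'   CS+ peak increment and Gaussian tuning width (deg).
#' @slot phase1,phase2 sinusoid phases (rad) at f0 and 2 f0.
#' @slot topoKappa occipital topography concentration (von-Mises-like).
#' @slot noiseExponent,noiseScale 1/f^a slope and broadband noise SD (uV).
#' @slot subjectSd between-subject log-amplitude SD (lognormal gain).
#' @slot ratingFloor,ratingGradient,ratingContextOffset,ratingSubjectSd,ratingNoiseSd
#'   US-expectancy model on the 0-100 scale.
#' @slot pupilGainMm,pupilContextOffsetMm,pupilNoiseSd,blinkRateHz pupil model.
#' @slot trialsPerCell presentations per orientation (x context) cell.
#' @slot seed integer master seed.
#' @export
setClass("GenParams",
  representation(nSubjects = "integer", f0Hz = "numeric",
    a1Base = "numeric", a1ContextOffset = "numeric",
    a2Base = "numeric", a2GradientPeak = "numeric",
    a2GradientWidthDeg = "numeric",
    phase1 = "numeric", phase2 = "numeric", topoKappa = "numeric",
    noiseExponent = "numeric", noiseScale = "numeric", subjectSd = "numeric",
    ratingFloor = "numeric", ratingGradient = "numeric",
    ratingContextOffset = "numeric", ratingSubjectSd = "numeric",
    ratingNoiseSd = "numeric",
    pupilGainMm = "numeric", pupilContextOffsetMm = "numeric",
    pupilNoiseSd = "numeric", blinkRateHz = "numeric",
    trialsPerCell = "integer", seed = "integer"))

setValidity("GenParams", function(object) {
  msg <- character()
  amps <- c(object@a1Base, object@a1ContextOffset, object@a2Base,
            object@a2GradientPeak, object@noiseScale)
  if (any(amps < 0)) msg <- c(msg, "all amplitudes must be >= 0")
  if (object@f0Hz <= 0) msg <- c(msg, "f0Hz must be > 0")
  if (object@blinkRateHz < 0 || object@blinkRateHz >= 1)
    msg <- c(msg, "blinkRateHz must lie in [0, 1)")
  if (object@trialsPerCell < 1L) msg <- c(msg, "trialsPerCell must be >= 1")
  if (length(msg)) msg else TRUE
})

#' EpochArray: epoched multichannel EEG
#'
#' Trials x sensors x samples array of scalp potentials (uV) or CSD values,
#' with the sampling rate, a per-sample time axis relative to cue onset, and
#' per-trial condition labels.
#'
#' @slot data numeric array (trials x sensors x samples).
#' @slot sfreq sampling frequency in Hz.
#' @slot timesMs numeric vector, per-sample time (ms) relative to cue onset.
#' @slot labels data.frame with one row per trial: orientation_deg, context,
#'   phase, half (1, 2 or NA).
#' @slot sensorIds character, matching a SensorNet.
#' @export
setClass("EpochArray",
  representation(data = "array", sfreq = "numeric", timesMs = "numeric",
                 labels = "data.frame", sensorIds = "character"))

setValidity("EpochArray", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L)
    return("data must be a 3-d array (trials x sensors x samples)")
  if (length(object@timesMs) != d[3])
    msg <- c(msg, "timesMs length must equal the sample dimension")
  else if (d[3] > 1) {
    dt <- diff(object@timesMs)
    if (any(dt <= 0) || any(abs(dt - 1000 / object@sfreq) > 1e-6))
      msg <- c(msg, "timesMs must be strictly increasing at 1000/sfreq steps")
  }
  if (nrow(object@labels) != d[1])
    msg <- c(msg, "labels must have one row per trial")
  if (length(object@sensorIds) != d[2])
    msg <- c(msg, "sensorIds length must equal the sensor dimension")
  if (length(msg)) msg else TRUE
})

#' ArtifactReport: outcome of SCADS-style statistical screening
#'
#' @slot sensorFlags logical matrix (trials x sensors), flagged as artifact.
#' @slot interpolated logical matrix, flagged sensors slated for (or already
#'   replaced by) spherical-spline interpolation.
#' @slot rejectedTrials integer indices of trials with more contaminated
#'   sensors than \code{maxBadSensors}.
#' @slot stats list of three (trials x sensors) matrices: absMax, sd, maxDiff.
#' @slot params list echoing the screening parameters.
#' @export
setClass("ArtifactReport",
  representation(sensorFlags = "matrix", interpolated = "matrix",
                 rejectedTrials = "integer", stats = "list",
                 params = "list"))

setValidity("ArtifactReport", function(object) {
  msg <- character()
  if (any(object@interpolated & !object@sensorFlags))
    msg <- c(msg, "interpolated must be a subset of sensorFlags")
  nb <- rowSums(object@sensorFlags)
  mb <- object@params$maxBadSensors
  if (!is.null(mb)) {
    should <- which(nb > mb)
    if (!setequal(should, object@rejectedTrials))
      msg <- c(msg, "rejectedTrials must be exactly the trials with flagged-sensor count > maxBadSensors")
  }
  if (length(msg)) msg else TRUE
})

#' ConditionAverage: per-condition mean waveforms
#'
#' @slot data numeric array (conditions x sensors x samples).
#' @slot conditions data.frame describing each condition (one row per
#'   condition; grouping label columns plus n_trials).
#' @slot sfreq sampling frequency (Hz).
#' @slot timesMs per-sample times (ms) relative to cue onset.
#' @slot sensorIds character.
#' @slot units "uV" for scalp potential, "CSD" after the surface Laplacian.
#' @export
setClass("ConditionAverage",
  representation(data = "array", conditions = "data.frame", sfreq = "numeric",
                 timesMs = "numeric", sensorIds = "character",
                 units = "character"))

setValidity("ConditionAverage", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L)
    return("data must be (conditions x sensors x samples)")
  if (nrow(object@conditions) != d[1])
    msg <- c(msg, "conditions must have one row per condition")
  if (!("n_trials" %in% names(object@conditions)))
    msg <- c(msg, "conditions must carry an n_trials column")
  else if (any(object@conditions$n_trials < 1))
    msg <- c(msg, "every retained condition must average >= 1 trial")
  if (length(object@sensorIds) != d[2])
    msg <- c(msg, "sensorIds length must equal the sensor dimension")
  if (length(msg)) msg else TRUE
})

#' PowerSpectrum: FFT power per condition and sensor
#'
#' Power is normalized so that a unit-amplitude sinusoid exactly on a bin
#' yields 0.5 (mean-square convention); summed over all bins it satisfies
#' Parseval's identity with the mean square of the windowed series.
#'
#' @slot power numeric array (conditions x sensors x bins), >= 0.
#' @slot conditions data.frame, as in ConditionAverage.
#' @slot freqsHz bin centre frequencies.
#' @slot binWidthHz spectral resolution.
#' @slot windowMs the (start, end) of the analysis window actually used,
#'   after truncation to an integer number of alignment cycles.
#' @slot sensorIds character.
#' @export
setClass("PowerSpectrum",
  representation(power = "array", conditions = "data.frame",
                 freqsHz = "numeric", binWidthHz = "numeric",
                 windowMs = "numeric", sensorIds = "character"))

setValidity("PowerSpectrum", function(object) {
  msg <- character()
  if (any(object@power < 0)) msg <- c(msg, "power must be >= 0 everywhere")
  if (length(object@freqsHz) != dim(object@power)[3])
    msg <- c(msg, "freqsHz must match the bin dimension")
  else if (length(object@freqsHz) > 1) {
    df <- diff(object@freqsHz)
    if (any(abs(df - object@binWidthHz) > 1e-9))
      msg <- c(msg, "freqsHz must be uniform with spacing binWidthHz")
  }
  if (length(msg)) msg else TRUE
})

#' PupilTraceSet: per-trial pupil diameter traces
#'
#' @slot traces numeric matrix (trials x samples), diameter in mm; missing
#'   samples (blinks / tracking loss) are NA until interpolated.
#' @slot missingMask logical matrix marking the originally missing samples.
#' @slot timesMs per-sample times relative to cue onset.
#' @slot sfreq sampling frequency (60 Hz).
#' @slot labels per-trial data.frame (orientation_deg, context, phase).
#' @export
setClass("PupilTraceSet",
  representation(traces = "matrix", missingMask = "matrix",
                 timesMs = "numeric", sfreq = "numeric",
                 labels = "data.frame"))

setValidity("PupilTraceSet", function(object) {
  msg <- character()
  if (!all(dim(object@traces) == dim(object@missingMask)))
    msg <- c(msg, "traces and missingMask must have identical dimensions")
  if (length(object@timesMs) != ncol(object@traces))
    msg <- c(msg, "timesMs must match the sample dimension")
  else if (length(object@timesMs) > 1) {
    dt <- diff(object@timesMs)
    if (any(abs(dt - 1000 / object@sfreq) > 1e-6))
      msg <- c(msg, "timesMs must be uniform at 1000/sfreq")
  }
  if (nrow(object@labels) != nrow(object@traces))
    msg <- c(msg, "labels must have one row per trial")
  if (length(msg)) msg else TRUE
})

#' WeightModel: a pre-specified cue-pattern contrast
#'
#' Seven zero-sum weights over the orientations +15..+75 deg (the -45 deg
#' cue is not covered by the published vectors and is excluded from the
#' Bayesian models). "sharpening" is a difference-of-Gaussians lateral
#' inhibition pattern; "generalization" a quadratic similarity trend.
#'
#' @slot name "sharpening" or "generalization".
#' @slot levels the seven orientations the weights refer to.
#' @slot weights numeric(7), summing to zero.
#' @export
setClass("WeightModel",
  representation(name = "character", levels = "numeric", weights = "numeric"))

setValidity("WeightModel", function(object) {
  msg <- character()
  if (length(object@weights) != 7L || length(object@levels) != 7L)
    msg <- c(msg, "a weight model has exactly 7 levels and 7 weights")
  else if (abs(sum(object@weights)) > 1e-12)
    msg <- c(msg, "weights must sum to 0 (tol 1e-12)")
  if (length(msg)) msg else TRUE
})

#' AnovaResult: repeated-measures ANOVA with sphericity correction
#'
#' @slot effects data.frame, one row per effect: effect, F, df1_unc, df2_unc,
#'   epsilon, df1_corr, df2_corr, p, pes, pes_lo, pes_hi, ss_effect, ss_error.
#' @export
setClass("AnovaResult", representation(effects = "data.frame"))

#' TTestResult: paired t with Cohen's d and a noncentral-t CI
#'
#' @slot t,df,p test statistic, degrees of freedom, probability.
#' @slot d Cohen's d for paired designs, d = t / sqrt(n).
#' @slot dLo,dHi 95 percent noncentral-t confidence bounds on d.
#' @slot n number of pairs.
#' @export
setClass("TTestResult",
  representation(t = "numeric", df = "numeric", p = "numeric", d = "numeric",
                 dLo = "numeric", dHi = "numeric", n = "integer"))

setValidity("TTestResult", function(object) {
  msg <- character()
  if (object@dLo > object@dHi) msg <- c(msg, "CI endpoints must be ordered")
  if (object@d < object@dLo - 1e-9 || object@d > object@dHi + 1e-9)
    msg <- c(msg, "d must lie inside its CI")
  if (length(msg)) msg else TRUE
})

#' BFMap: log Bayes-factor topographies
#'
#' @slot map data.frame with columns sensor, frequency_hz, model, log_bf
#'   (natural log, candidate vs null; cue-pattern models are transitive
#'   comparisons against the context-only model through the common null).
#' @export
setClass("BFMap", representation(map = "data.frame"))

setValidity("BFMap", function(object) {
  need <- c("sensor", "frequency_hz", "model", "log_bf")
  if (!all(need %in% names(object@map)))
    return(paste("map must have columns:", paste(need, collapse = ", ")))
  TRUE
})
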