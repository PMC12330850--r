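#' Generate epoched synthetic ssVEP EEG for one subject
#'
#' Per trial the cue-locked signal is
#' \deqn{s(t) = a_1 \cos(2\pi f_0 t + \phi_1) + a_2 \cos(2\pi 2 f_0 t + \phi_2)}
#' present only while the cue is on (t in [0, duration)), where
#' \eqn{a_1 = a_{1base} (+ a_{1ctx}\ \mathrm{if\ aversive})} and
#' \eqn{a_2 = a_{2base} + a_{2peak} \exp(-\Delta\theta^2 / (2 w^2))} with
#' \eqn{\Delta\theta} the orientation distance from the CS+. The signal is
#' spatially weighted by an occipitally peaked von-Mises-like topography and
#' superimposed on independent 1/f background noise per sensor and trial.
#' Both amplitudes are multiplied by a subject-specific lognormal gain.
#' Epochs span -600..+3900 ms around cue onset at 500 Hz. The output is
#' deterministic given (params@seed, subjectId).
#'
#' @param schedule a non-empty \linkS4class{TrialSchedule}.
#' @param params a \linkS4class{GenParams}.
#' @param net a \linkS4class{SensorNet}.
#' @param subjectId integer subject index.
#' @param sfreq sampling rate (Hz), default 500.
#' @param windowMs epoch window (ms) relative to cue onset.
#' @return an \linkS4class{EpochArray} labelled from the schedule.
#' @export
generateEegEpochs <- function(schedule, params, net, subjectId,
                              sfreq = 500, windowMs = c(-600, 3900)) {
  rec <- scheduleRecords(schedule)
  if (!nrow(rec)) stop("schedule must be non-empty")
  validObject(params)
  nSamp <- as.integer(round((windowMs[2] - windowMs[1]) / 1000 * sfreq))
  times <- windowMs[1] + (seq_len(nSamp) - 1L) * 1000 / sfreq
  tSec <- times / 1000
  nSens <- length(sensorIds(net))
  nTr <- nrow(rec)

  topo <- occipitalTopography(net, params@topoKappa)
  withSeed(deriveSeed(params@seed, "eeg", subjectId), {
    gain <- exp(stats::rnorm(1, 0, params@subjectSd))
    grad <- orientationGradient(rec$orientation_deg, params@a2GradientWidthDeg)
    a1 <- gain * (params@a1Base +
                    params@a1ContextOffset * (rec$context == "aversive"))
    a2 <- gain * (params@a2Base + params@a2GradientPeak * grad)
    cueOn <- tSec >= 0 & tSec < rec$duration_s[1]
    carrier1 <- cos(2 * pi * params@f0Hz * tSec + params@phase1) * cueOn
    carrier2 <- cos(2 * pi * 2 * params@f0Hz * tSec + params@phase2) * cueOn

    dat <- array(0, dim = c(nTr, nSens, nSamp))
    for (tr in seq_len(nTr)) {
      sig <- a1[tr] * carrier1 + a2[tr] * carrier2     # 1 x samples
      noise <- oneOverFNoise(nSamp, nSens, sfreq, params@noiseExponent,
                             params@noiseScale)        # samples x sensors
      dat[tr, , ] <- t(noise) + outer(topo, sig)
    }
    labels <- data.frame(orientation_deg = rec$orientation_deg,
                         context = rec$context, phase = rec$phase,
                         half = NA_integer_)
    new("EpochArray", data = dat, sfreq = sfreq, timesMs = times,
        labels = labels, sensorIds = sensorIds(net))
  })
}

#' Occipitally peaked spatial weighting of the ssVEP signal
#'
#' Von-Mises-like kernel on the sphere, centred on the pool's Oz sensor
#' (E75): \eqn{w_i = \exp(\kappa (\cos\gamma_i - 1))} with \eqn{\gamma_i}
#' the angle between sensor i and Oz. Weight 1 at Oz, decaying with angular
#' distance.
#'
#' @param net a SensorNet.
#' @param kappa concentration parameter.
#' @return numeric vector of per-sensor weights in (0, 1].
#' @export
occipitalTopography <- function(net, kappa = 10) {
  pos <- net@positions
  oz <- pos[match(net@occipitalPool[1], net@sensorIds), ]
  cosg <- as.vector(pos %*% oz)
  exp(kappa * (cosg - 1))
}

#' Inject labelled artifacts into an EpochArray
#'
#' Adds artifacts at the locations given in \code{spec}, a data.frame with
#' columns trial, sensor (index or id), kind ("spike", "drift", "flatline")
#' and magnitude (uV). A spike adds a one-sample-wide triangular transient
#' of the given height mid-epoch; a drift adds a linear ramp from 0 to
#' magnitude; a flatline replaces the channel by its own mean. The input is
#' copied, never modified; ground truth stays with the caller's spec.
#'
#' @param epochs an EpochArray.
#' @param spec artifact specification data.frame.
#' @param seed integer; randomizes the spike sample position only.
#' @return a new EpochArray with artifacts added.
#' @export
injectArtifacts <- function(epochs, spec, seed = 1L) {
  dat <- epochs@data
  if (!nrow(spec)) return(epochs)
  d <- dim(dat)
  sens <- spec$sensor
  if (is.character(sens)) sens <- match(sens, epochs@sensorIds)
  if (any(spec$trial < 1 | spec$trial > d[1]) ||
      any(is.na(sens)) || any(sens < 1 | sens > d[2]))
    stop("artifact spec contains out-of-range trial or sensor indices")
  withSeed(deriveSeed(seed, "artifacts"), {
    for (i in seq_len(nrow(spec))) {
      tr <- spec$trial[i]; se <- sens[i]; mag <- spec$magnitude[i]
      kind <- spec$kind[i]
      if (kind == "spike") {
        at <- sample(seq(d[3] %/% 4, 3 * d[3] %/% 4), 1)
        idx <- max(1, at - 2):min(d[3], at + 2)
        shape <- mag * (1 - abs(seq_along(idx) - which(idx == at)) / 3)
        dat[tr, se, idx] <- dat[tr, se, idx] + shape
      } else if (kind == "drift") {
        dat[tr, se, ] <- dat[tr, se, ] + seq(0, mag, length.out = d[3])
      } else if (kind == "flatline") {
        dat[tr, se, ] <- mean(dat[tr, se, ])
      } else stop("unknown artifact kind: ", kind)
    }
  })
  initialize(epochs, data = dat)
}
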