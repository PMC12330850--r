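#' Extract cue-locked epochs from a continuous recording
#'
#' @param continuous numeric matrix (sensors x samples) of a continuous
#'   recording.
#' @param onsetsS event onsets in seconds from recording start.
#' @param sfreq sampling rate (Hz).
#' @param windowMs epoch window (ms) relative to onset, default
#'   c(-600, 3900). The sample at t = 0 is the first sample at-or-after the
#'   event onset.
#' @param labels optional per-event data.frame carried into the epochs.
#' @param sensorIds optional channel labels.
#' @return an \linkS4class{EpochArray}.
#' @export
extractEpochs <- function(continuous, onsetsS, sfreq,
                          windowMs = c(-600, 3900), labels = NULL,
                          sensorIds = NULL) {
  nSamp <- as.integer(round((windowMs[2] - windowMs[1]) / 1000 * sfreq))
  preSamp <- as.integer(round(-windowMs[1] / 1000 * sfreq))
  onsetIdx <- as.integer(ceiling(onsetsS * sfreq)) + 1L  # first sample >= onset
  first <- onsetIdx - preSamp
  last <- first + nSamp - 1L
  bad <- which(first < 1L | last > ncol(continuous))
  if (length(bad))
    stop("epoch window truncated for event(s) ", paste(bad, collapse = ", "))
  nSens <- nrow(continuous)
  dat <- array(0, dim = c(length(onsetsS), nSens, nSamp))
  for (e in seq_along(onsetsS))
    dat[e, , ] <- continuous[, first[e]:last[e], drop = FALSE]
  if (is.null(labels))
    labels <- data.frame(orientation_deg = rep(NA_real_, length(onsetsS)),
                         context = NA_character_, phase = NA_character_,
                         half = NA_integer_)
  if (is.null(sensorIds)) sensorIds <- paste0("E", seq_len(nSens))
  times <- windowMs[1] + (seq_len(nSamp) - 1L) * 1000 / sfreq
  new("EpochArray", data = dat, sfreq = sfreq, timesMs = times,
      labels = labels, sensorIds = sensorIds)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering applied per trial
#' and sensor. The default 4th-order filter, applied twice, attenuates
#' a 2 x cutoff component by far more than 40 dB (the effective roll-off of
#' the squared magnitude response is 48 dB/octave).
#'
#' @param epochs an EpochArray.
#' @param cutoffHz low-pass cutoff (Hz); must be below Nyquist.
#' @param order filter order, default 4 (applied forward and backward).
#' @return a filtered EpochArray.
#' @export
lowpassFilter <- function(epochs, cutoffHz = 40, order = 4) {
  if (cutoffHz >= epochs@sfreq / 2)
    stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoffHz / (epochs@sfreq / 2), type = "low")
  dat <- epochs@data
  d <- dim(dat)
  flat <- matrix(aperm(dat, c(3, 1, 2)), nrow = d[3])  # samples x (trial*sensor)
  flat <- filtfiltMat(bf$b, bf$a, flat)
  dat <- aperm(array(flat, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  initialize(epochs, data = dat)
}

# zero-phase IIR filtering of every column of X at once: reflection padding,
# forward and backward passes with a transposed direct-form-II recursion
# vectorized across columns (the per-column recursion is the hot loop of the
# pipeline)
filtfiltMat <- function(b, a, X) {
  X <- as.matrix(X)
  m <- max(length(a), length(b))
  b <- c(b, rep(0, m - length(b)))
  a <- c(a, rep(0, m - length(a)))
  np <- 3L * (m - 1L)
  n <- nrow(X)
  if (n <= np + 1L) stop("series too short for the filter order")
  head <- 2 * matrix(X[1L, ], np, ncol(X), byrow = TRUE) -
    X[(np + 1L):2L, , drop = FALSE]
  tail <- 2 * matrix(X[n, ], np, ncol(X), byrow = TRUE) -
    X[(n - 1L):(n - np), , drop = FALSE]
  Y <- rbind(head, X, tail)
  Y <- filterMat(b, a, Y)
  Y <- filterMat(b, a, Y[nrow(Y):1L, , drop = FALSE])
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(np + 1L):(np + n), , drop = FALSE]
}

# stationary filter state for a unit constant input (removes startup
# transients when combined with reflection padding)
filterZi <- function(b, a) {
  m <- length(b)
  G <- sum(b) / sum(a)                     # DC gain
  zi <- numeric(m - 1L)
  zi[m - 1L] <- b[m] - a[m] * G
  if (m > 2L)
    for (k in (m - 2L):1L) zi[k] <- zi[k + 1L] + b[k + 1L] - a[k + 1L] * G
  zi
}

filterMat <- function(b, a, X) {
  m <- length(b)
  n <- nrow(X)
  nc <- ncol(X)
  Xt <- t(X)                       # channels x samples: contiguous access
  Yt <- matrix(0, nc, n)
  zi <- filterZi(b, a)
  z <- vector("list", m - 1L)
  for (k in seq_len(m - 1L)) z[[k]] <- zi[k] * Xt[, 1L]
  for (t in seq_len(n)) {
    xt <- Xt[, t]
    yt <- b[1L] * xt + z[[1L]]
    if (m > 2L) {
      for (k in seq_len(m - 2L))
        z[[k]] <- b[k + 1L] * xt - a[k + 1L] * yt + z[[k + 1L]]
    }
    z[[m - 1L]] <- b[m] * xt - a[m] * yt
    Yt[, t] <- yt
  }
  t(Yt)
}

#' SCADS-style statistical artifact screening
#'
#' For every (trial, sensor) the three screening statistics are computed
#' over samples: maximum absolute value, standard deviation, and maximum of
#' successive absolute differences. Each statistic is robust-z-scored
#' (median/MAD) twice: against its distribution over trials within each
#' sensor, and over sensors within each trial. A sensor-trial is flagged
#' when any |z| exceeds \code{zThreshold}; trials with more than
#' \code{maxBadSensors} flagged sensors are rejected outright, the
#' remaining flags are marked for spherical-spline interpolation.
#'
#' @param epochs an EpochArray with >= 2 trials.
#' @param net a SensorNet (sensor identity check).
#' @param zThreshold robust-z cutoff, default 3.
#' @param maxBadSensors rejection threshold on the flagged-sensor count per
#'   trial, default 20 (out of 129 in the reference layout).
#' @return an \linkS4class{ArtifactReport}.
#' @export
scadsScreen <- function(epochs, net = NULL, zThreshold = 3,
                        maxBadSensors = 20L) {
  d <- dim(epochs@data)
  if (d[1] < 2L) stop("need at least 2 trials to screen against")
  if (!is.null(net) && !identical(sensorIds(net), epochs@sensorIds))
    stop("sensor net does not match the epochs")
  dat <- epochs@data
  absMax <- apply(dat, c(1, 2), function(x) max(abs(x)))
  sdv <- apply(dat, c(1, 2), stats::sd)
  maxDiff <- apply(dat, c(1, 2), function(x) max(abs(diff(x))))
  flags <- robustFlag(absMax, zThreshold) | robustFlag(sdv, zThreshold) |
    robustFlag(maxDiff, zThreshold)
  nBad <- rowSums(flags)
  rejected <- which(nBad > maxBadSensors)
  interp <- flags
  interp[rejected, ] <- FALSE
  new("ArtifactReport", sensorFlags = flags, interpolated = interp,
      rejectedTrials = as.integer(rejected),
      stats = list(absMax = absMax, sd = sdv, maxDiff = maxDiff),
      params = list(zThreshold = zThreshold,
                    maxBadSensors = as.integer(maxBadSensors),
                    rejectedFraction = length(rejected) / d[1]))
}

# robust |z| > thr in either direction of comparison:
# across trials within sensor (columns) and across sensors within trial (rows)
robustFlag <- function(m, thr) {
  zCol <- robustZ(m, margin = 2L)
  zRow <- robustZ(m, margin = 1L)
  abs(zCol) > thr | abs(zRow) > thr
}

robustZ <- function(m, margin) {
  med <- apply(m, margin, stats::median)
  madv <- apply(m, margin, stats::mad)
  madv[madv < 1e-12] <- 1e-12
  if (margin == 2L) sweep(sweep(m, 2, med), 2, madv, "/")
  else sweep(sweep(m, 1, med), 1, madv, "/")
}

#' Replace flagged sensors by spherical-spline interpolated values
#'
#' Per flagged trial, the contaminated channels are re-estimated sample-wise
#' from the unflagged channels by spherical-spline interpolation (order
#' m = 4), the classical scalp-potential spline on the unit sphere. The
#' statistical weighting hook (\code{weights}) defaults to uniform.
#' Unflagged channels are returned bit-unchanged; rejected trials are left
#' untouched (they are excluded at averaging).
#'
#' @param epochs an EpochArray.
#' @param report an ArtifactReport from \code{scadsScreen}.
#' @param net a SensorNet supplying the spline geometry.
#' @param m spline order, default 4.
#' @param nTerms Legendre series length, default 50.
#' @param lambda small ridge on the spline system for numerical stability.
#' @param weights optional per-sensor statistical weights (currently
#'   uniform; exposed as a hook).
#' @return an EpochArray with flagged channels replaced.
#' @export
interpolateSensors <- function(epochs, report, net, m = 4, nTerms = 50,
                               lambda = 1e-8, weights = NULL) {
  stopifnot(identical(sensorIds(net), epochs@sensorIds))
  dat <- epochs@data
  d <- dim(dat)
  todo <- which(rowSums(report@interpolated) > 0L)
  if (!length(todo)) return(epochs)
  cosg <- tcrossprod(net@positions)
  cosg[cosg > 1] <- 1; cosg[cosg < -1] <- -1
  G <- splineGMatrix(cosg, m, nTerms)
  for (tr in todo) {
    bad <- which(report@interpolated[tr, ])
    good <- setdiff(seq_len(d[2]), bad)
    if (!length(good)) stop("all sensors flagged in trial ", tr)
    Ggg <- G[good, good, drop = FALSE]
    A <- rbind(cbind(Ggg + diag(lambda, length(good)), 1),
               c(rep(1, length(good)), 0))
    rhs <- rbind(matrix(dat[tr, good, ], nrow = length(good)),
                 rep(0, d[3]))
    sol <- solve(A, rhs)
    cc <- sol[seq_along(good), , drop = FALSE]
    c0 <- sol[length(good) + 1L, ]
    est <- G[bad, good, drop = FALSE] %*% cc +
      matrix(c0, length(bad), d[3], byrow = TRUE)
    dat[tr, bad, ] <- est
  }
  initialize(epochs, data = dat)
}

# spherical-spline kernel matrix g(cos gamma), Perrin-style series
splineGMatrix <- function(cosg, m, nTerms) {
  n <- seq_len(nTerms)
  coef <- (2 * n + 1) / (n^m * (n + 1)^m)
  P <- legendreP(as.vector(cosg), nTerms)
  matrix(P %*% coef / (4 * pi), nrow = nrow(cosg))
}

#' Average artifact-free trials per condition
#'
#' @param epochs an EpochArray.
#' @param grouping label columns defining a condition, default
#'   c("orientation_deg", "context").
#' @param report optional ArtifactReport; its rejected trials are excluded.
#' @return a \linkS4class{ConditionAverage} (conditions present in the data
#'   only; empty conditions are naturally absent and surface through the
#'   empty-cell exclusion rule).
#' @export
averageConditions <- function(epochs,
                              grouping = c("orientation_deg", "context"),
                              report = NULL) {
  keep <- seq_len(nTrials(epochs))
  if (!is.null(report) && length(report@rejectedTrials))
    keep <- setdiff(keep, report@rejectedTrials)
  if (!length(keep)) stop("no trials retained")
  lab <- epochs@labels[keep, grouping, drop = FALSE]
  key <- do.call(paste, c(lab, sep = "\r"))
  ukey <- unique(key)
  d <- dim(epochs@data)
  out <- array(0, dim = c(length(ukey), d[2], d[3]))
  nTr <- integer(length(ukey))
  for (i in seq_along(ukey)) {
    idx <- keep[key == ukey[i]]
    nTr[i] <- length(idx)
    sub <- epochs@data[idx, , , drop = FALSE]
    out[i, , ] <- colMeans(sub, dims = 1)
  }
  conds <- lab[match(ukey, key), , drop = FALSE]
  rownames(conds) <- NULL
  conds$n_trials <- nTr
  new("ConditionAverage", data = out, conditions = conds,
      sfreq = epochs@sfreq, timesMs = epochs@timesMs,
      sensorIds = epochs@sensorIds, units = "uV")
}

#' Split acquisition trials into halves and apply the empty-cell rule
#'
#' Assigns the half label by trial order: the first ceiling(n/2) retained
#' and rejected trials alike go to half 1, the rest to half 2 (the split is
#' by position in the acquisition sequence, not by retained count). The
#' participant is excluded from the acquisition Cue x Time analysis when any
#' orientation x half cell holds zero retained trials.
#'
#' @param epochs acquisition-phase EpochArray.
#' @param report optional ArtifactReport defining the retained trials.
#' @return list(epochs = relabelled EpochArray, participantExcluded =
#'   logical).
#' @export
splitHalvesAndScreen <- function(epochs, report = NULL) {
  n <- nTrials(epochs)
  half <- rep(2L, n)
  half[seq_len(ceiling(n / 2))] <- 1L
  lab <- epochs@labels
  lab$half <- half
  out <- initialize(epochs, labels = lab)
  keep <- seq_len(n)
  if (!is.null(report) && length(report@rejectedTrials))
    keep <- setdiff(keep, report@rejectedTrials)
  cells <- expand.grid(orientation_deg = unique(lab$orientation_deg),
                       half = c(1L, 2L))
  have <- unique(lab[keep, c("orientation_deg", "half")])
  excluded <- nrow(merge(cells, have)) < nrow(cells)
  list(epochs = out, participantExcluded = excluded)
}
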