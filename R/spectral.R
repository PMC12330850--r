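#' FFT power spectrum on a cycle-aligned analysis window
#'
#' Restricts the waveforms to \code{windowMs} (default 600-3900 ms after cue
#' onset, dropping the initial non-stationary ssVEP build-up), truncates the
#' window to the largest integer number of cycles of
#' \code{alignCyclesToHz} so that the tagged frequency and its harmonics
#' fall exactly on FFT bins (3300 ms -> 3200 ms at 7.5 Hz and 500 Hz
#' sampling: bin width 0.3125 Hz, 7.5 Hz = bin 24, 15 Hz = bin 48), removes
#' the window mean, and returns squared-magnitude power normalized so a
#' unit-amplitude bin-aligned sinusoid yields 0.5 (mean-square convention;
#' summed over bins the power satisfies Parseval's identity with the
#' windowed series).
#'
#' @param avg a \linkS4class{ConditionAverage} (typically CSD-transformed).
#' @param windowMs requested analysis window (ms) after cue onset.
#' @param alignCyclesToHz frequency whose cycles the window is aligned to.
#' @return a \linkS4class{PowerSpectrum}.
#' @export
computePowerSpectrum <- function(avg, windowMs = c(600, 3900),
                                 alignCyclesToHz = 7.5) {
  times <- avg@timesMs
  if (windowMs[1] < min(times) || windowMs[2] > max(times) + 1000 / avg@sfreq)
    stop("analysis window outside the epoch")
  cycleMs <- 1000 / alignCyclesToHz
  nCycles <- floor((windowMs[2] - windowMs[1]) / cycleMs)
  if (nCycles < 1) stop("window shorter than one cycle of the alignment frequency")
  usedMs <- c(windowMs[1], windowMs[1] + nCycles * cycleMs)
  idx <- which(times >= usedMs[1] - 1e-9 & times < usedMs[2] - 1e-9)
  N <- length(idx)
  d <- dim(avg@data)
  nBins <- N %/% 2 + 1L
  pow <- array(0, dim = c(d[1], d[2], nBins))
  for (cc in seq_len(d[1])) {
    x <- avg@data[cc, , idx, drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    x <- x - rowMeans(x)
    X <- t(stats::mvfft(t(x)))[, seq_len(nBins), drop = FALSE]
    p <- 2 * Mod(X)^2 / N^2
    p[, 1] <- Mod(X[, 1])^2 / N^2                    # DC
    if (N %% 2 == 0) p[, nBins] <- Mod(X[, nBins])^2 / N^2  # Nyquist
    pow[cc, , ] <- p
  }
  freqs <- (seq_len(nBins) - 1L) * avg@sfreq / N
  new("PowerSpectrum", power = pow, conditions = avg@conditions,
      freqsHz = freqs, binWidthHz = avg@sfreq / N, windowMs = usedMs,
      sensorIds = avg@sensorIds)
}

#' Neighbour-bin signal-to-noise ratio at a tagged frequency
#'
#' SNR = power at the target bin divided by the mean power at the six
#' adjacent bins, offsets +-2, +-3, +-4 (the two immediate neighbours +-1
#' are left out). The target must coincide with a bin.
#'
#' @param spectrum a PowerSpectrum.
#' @param targetHz target frequency (must lie on a bin within
#'   1e-6 x bin width).
#' @param nNoiseBinsPerSide noise bins per side, default 3.
#' @param skipImmediate immediate neighbours skipped per side, default 1.
#' @return matrix (conditions x sensors) of SNR values, dimnames carrying
#'   condition keys and sensor ids.
#' @export
snrAt <- function(spectrum, targetHz, nNoiseBinsPerSide = 3,
                  skipImmediate = 1) {
  bw <- spectrum@binWidthHz
  k <- (targetHz - spectrum@freqsHz[1]) / bw
  if (abs(k - round(k)) > 1e-6)
    stop("target frequency does not fall on a spectral bin")
  k <- as.integer(round(k)) + 1L
  off <- (skipImmediate + 1):(skipImmediate + nNoiseBinsPerSide)
  nb <- c(k - off, k + off)
  if (any(nb < 1L) || any(nb > length(spectrum@freqsHz)))
    stop("noise bins out of spectral range for target ", targetHz, " Hz")
  d <- dim(spectrum@power)
  tgt <- matrix(spectrum@power[, , k], d[1], d[2])
  noise <- apply(spectrum@power[, , nb, drop = FALSE], c(1, 2), mean)
  snr <- tgt / noise
  rownames(snr) <- do.call(paste, c(spectrum@conditions[
    setdiff(names(spectrum@conditions), "n_trials")], sep = "/"))
  colnames(snr) <- spectrum@sensorIds
  snr
}

#' Pool SNR over the occipital sensor cluster
#'
#' Arithmetic mean of per-sensor SNR over the eight-sensor occipital pool
#' (Oz and seven neighbours).
#'
#' @param snrPerSensor matrix (conditions x sensors) from \code{snrAt}, or a
#'   named numeric vector of per-sensor values.
#' @param net a SensorNet whose pool sensors must all be present.
#' @return numeric vector, one pooled SNR per condition.
#' @export
poolSensors <- function(snrPerSensor, net) {
  if (is.null(dim(snrPerSensor)))
    snrPerSensor <- matrix(snrPerSensor, nrow = 1,
                           dimnames = list(NULL, names(snrPerSensor)))
  pool <- occipitalPool(net)
  missing <- setdiff(pool, colnames(snrPerSensor))
  if (length(missing))
    stop("pool sensor(s) missing: ", paste(missing, collapse = ", "))
  rowMeans(snrPerSensor[, pool, drop = FALSE])
}
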