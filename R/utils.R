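#' Derive a reproducible sub-seed from a master seed
#'
#' Fans a single pipeline seed out to per-module, per-subject random streams
#' so each stage can be re-run in isolation. The derivation is a fixed
#' integer hash kept inside the 32-bit range.
#'
#' @param seed master integer seed.
#' @param stream character stream label (e.g. "eeg", "pupil").
#' @param id integer sub-index (e.g. subject id), default 0.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
deriveSeed <- function(seed, stream, id = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  val <- (as.double(seed) %% 2147483647) * 69621 + h * 7919 + as.double(id) * 104729
  as.integer(val %% 2147483629)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Legendre polynomials P_1..P_nmax at given abscissae
#'
#' Bonnet recurrence; returns a (length(x) x nmax) matrix. Used by the
#' spherical-spline machinery (CSD and bad-sensor interpolation).
#'
#' @param x numeric vector in [-1, 1].
#' @param nmax highest degree.
#' @return matrix with column n holding P_n(x).
#' @keywords internal
legendreP <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pm1 <- rep(1, length(x))     # P_0
  p <- x                       # P_1
  out[, 1] <- p
  if (nmax >= 2) {
    for (n in 2:nmax) {
      pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
      out[, n] <- pn
      pm1 <- p
      p <- pn
    }
  }
  out
}

#' Gaussian generalization gradient over orientation distance from CS+
#'
#' @param orientationDeg cue orientations (deg).
#' @param widthDeg Gaussian tuning width (deg).
#' @return values in (0, 1], 1 at the CS+ (+45 deg).
#' @export
orientationGradient <- function(orientationDeg, widthDeg) {
  dtheta <- abs(orientationDeg - CS_PLUS_DEG)
  exp(-dtheta^2 / (2 * widthDeg^2))
}

# 1/f^alpha noise, one column per channel; exact target SD by construction
# of the spectral envelope (random phases, Rayleigh amplitudes).
oneOverFNoise <- function(nSamples, nChannels, sfreq, exponent, scale) {
  if (scale == 0) return(matrix(0, nSamples, nChannels))
  n <- nSamples
  nPos <- floor((n - 1) / 2)            # strictly positive, non-Nyquist bins
  freqs <- (1:nPos) * sfreq / n
  env <- freqs^(-exponent / 2)
  # expected variance of the synthesized series for a unit envelope multiplier
  # x = Re(ifft(X)); with X_k = c*env_k*(z1+iz2), z ~ N(0,1): var = 2*sum((c*env)^2)/n^2
  c0 <- sqrt(scale^2 * n^2 / (2 * sum(env^2)))
  re <- matrix(stats::rnorm(nPos * nChannels), nPos, nChannels)
  im <- matrix(stats::rnorm(nPos * nChannels), nPos, nChannels)
  X <- matrix(0 + 0i, n, nChannels)
  X[2:(nPos + 1), ] <- c0 * env * (re + 1i * im)
  X[n:(n - nPos + 1), ] <- Conj(X[2:(nPos + 1), ])
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
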