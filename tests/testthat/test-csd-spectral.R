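test_that("CSD maps constants to zero and is linear", {
  net <- smallNet(64)
  TT <- csdMatrix(net@positions)
  const <- rep(7.3, 64)
  expect_lt(max(abs(TT %*% const)), 1e-6 * 7.3)
  set.seed(21)
  for (i in 1:100) {
    v1 <- rnorm(64); v2 <- rnorm(64); a <- rnorm(1); b <- rnorm(1)
    expect_equal(as.vector(TT %*% (a * v1 + b * v2)),
                 as.vector(a * TT %*% v1 + b * TT %*% v2),
                 tolerance = 1e-10)
  }
})

test_that("a degree-2 spherical harmonic is an eigenfunction of the unregularized CSD", {
  net <- smallNet(129)
  pos <- net@positions
  TT <- csdMatrix(pos, lambda = 0)
  y2 <- sqrt(3) * pos[, 1] * pos[, 3]
  out <- as.vector(TT %*% y2)
  fit <- lm(out ~ 0 + y2)
  # surface-Laplacian eigenvalue of degree 2 is n(n+1) = 6, sign preserved
  expect_equal(unname(coef(fit)[1]), 6, tolerance = 0.05)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("Legendre evaluation agrees with pracma where pracma is stable", {
  skip_if_not_installed("pracma")
  # pracma::legendre loses accuracy near |x| = 1 at high degree; compare on
  # the interior, low-to-moderate degrees, where it is exact
  xs <- seq(-0.95, 0.95, length.out = 41)
  for (n in c(2, 7, 15, 25)) {
    pr <- vapply(xs, function(x) pracma::legendre(n, x)[1], 0)
    mine <- ssvepContext:::legendreP(xs, n)[, n]
    expect_equal(mine, pr, tolerance = 1e-6)
  }
})

test_that("CSD matches an independently assembled dense-matrix oracle", {
  net <- smallNet(40)
  pos <- net@positions
  lambda <- 0.2; m <- 4; L <- 50
  ## oracle: assemble G, H from first principles with an inline Bonnet
  ## recurrence (P_n(+-1) checked against the exact boundary identity)
  nS <- nrow(pos)
  cosg <- pmin(1, pmax(-1, tcrossprod(pos)))
  x <- as.vector(cosg)
  G0 <- matrix(0, nS, nS); H0 <- matrix(0, nS, nS)
  pm1 <- rep(1, length(x)); pcur <- x
  for (n in 1:L) {
    if (n > 1) {
      pnext <- ((2 * n - 1) * x * pcur - (n - 1) * pm1) / n
      pm1 <- pcur; pcur <- pnext
    }
    expect_equal(pcur[x == 1], rep(1, sum(x == 1)))  # boundary identity
    gn <- (2 * n + 1) / (n^m * (n + 1)^m)
    G0 <- G0 + gn * matrix(pcur, nS, nS)
    H0 <- H0 + gn * n * (n + 1) * matrix(pcur, nS, nS)
  }
  G0 <- G0 / (4 * pi); H0 <- H0 / (4 * pi)
  A <- rbind(cbind(G0 + diag(lambda, nS), 1), c(rep(1, nS), 0))
  set.seed(31)
  v <- rnorm(nS)
  sol <- solve(A, c(v, 0))          # direct bordered solve, no inverse
  oracle <- as.vector(H0 %*% sol[1:nS])
  mine <- as.vector(csdMatrix(pos, lambda, m, L) %*% v)
  expect_equal(mine, oracle, tolerance = 1e-8)
})

test_that("CSD transform requires enough sensors and rejects bad lambda", {
  net <- smallNet(34)
  m <- avgFromMatrix(matrix(rnorm(34 * 10), 34), sensorIds = sensorIds(net))
  expect_error(csdTransform(m, net, lambda = -1), "lambda")
  net16 <- egiSensorNet(16)
  m16 <- avgFromMatrix(matrix(rnorm(16 * 10), 16),
                       sensorIds = sensorIds(net16))
  expect_error(csdTransform(m16, net16), "32 sensors")
})

test_that("power spectrum concentrates bin-aligned sinusoids and respects Parseval", {
  times <- seq(-600, 3898, by = 2)
  x <- cos(2 * pi * 7.5 * times / 1000)
  sp <- computePowerSpectrum(avgFromMatrix(rbind(x, x * 0 + 1)))
  k75 <- which(abs(sp@freqsHz - 7.5) < 1e-9)
  k15 <- which(abs(sp@freqsHz - 15) < 1e-9)
  expect_equal(sp@binWidthHz, 0.3125)
  expect_equal(k75 - 1L, 24L)               # 7.5 Hz = bin 24
  expect_equal(sp@power[1, 1, k75], 0.5, tolerance = 1e-10)
  expect_lt(sp@power[1, 1, k15], 1e-10)
  expect_lt(sum(sp@power[1, 1, -k75]), 1e-10)
  # DC-only channel: no power anywhere after mean removal
  expect_lt(max(sp@power[1, 2, ]), 1e-20)
  # Parseval: total power equals the mean square of the windowed series
  set.seed(41)
  y <- rnorm(length(times))
  spy <- computePowerSpectrum(avgFromMatrix(rbind(y)))
  idx <- times >= 600 & times < 3800
  yc <- y[idx] - mean(y[idx])
  expect_equal(sum(spy@power[1, 1, ]), mean(yc^2), tolerance = 1e-8)
})

test_that("two-tone signal yields the 4:1 bin-power ratio against a direct DFT oracle", {
  times <- seq(-600, 3898, by = 2)
  x <- 2 * cos(2 * pi * 7.5 * times / 1000) + cos(2 * pi * 15 * times / 1000)
  sp <- computePowerSpectrum(avgFromMatrix(rbind(x)))
  k75 <- which(abs(sp@freqsHz - 7.5) < 1e-9)
  k15 <- which(abs(sp@freqsHz - 15) < 1e-9)
  expect_equal(sp@power[1, 1, k75] / sp@power[1, 1, k15], 4,
               tolerance = 1e-9)
  # direct DFT oracle on the windowed samples
  idx <- which(times >= 600 & times < 3800)
  w <- x[idx] - mean(x[idx]); N <- length(w); tt <- (seq_len(N) - 1) / 500
  for (fr in c(7.5, 15)) {
    X <- sum(w * exp(-2i * pi * fr * tt))
    k <- which(abs(sp@freqsHz - fr) < 1e-9)
    expect_equal(sp@power[1, 1, k], 2 * Mod(X)^2 / N^2, tolerance = 1e-10)
  }
})

test_that("spectrum errors on out-of-epoch or sub-cycle windows", {
  m <- avgFromMatrix(matrix(rnorm(2 * 2250), 2))
  expect_error(computePowerSpectrum(m, windowMs = c(600, 5000)), "outside")
  expect_error(computePowerSpectrum(m, windowMs = c(600, 700),
                                    alignCyclesToHz = 7.5), "cycle")
})

test_that("SNR reproduces hand-computable cases and a neighbour-enumeration oracle", {
  mkSpec <- function(powVec) {
    arr <- array(0, dim = c(1, 1, length(powVec)))
    arr[1, 1, ] <- powVec
    new("PowerSpectrum", power = arr,
        conditions = data.frame(orientation_deg = 45, context = "none",
                                n_trials = 1L),
        freqsHz = (seq_along(powVec) - 1) * 0.3125, binWidthHz = 0.3125,
        windowMs = c(600, 3800), sensorIds = "E1")
  }
  flat <- mkSpec(rep(3, 60))
  expect_equal(unname(snrAt(flat, 7.5)[1, 1]), 1)
  # target bin 12, all others 2 -> snr = 6
  pv <- rep(2, 60); pv[25] <- 12            # bin index 24 = 7.5 Hz
  expect_equal(unname(snrAt(mkSpec(pv), 7.5)[1, 1]), 6)
  # random spectrum vs independently coded neighbour enumeration
  set.seed(51)
  pv2 <- runif(80, 0.5, 4)
  got <- unname(snrAt(mkSpec(pv2), 15)[1, 1])
  k <- 48 + 1                               # 15 Hz = bin 48
  neigh <- c(k - 4, k - 3, k - 2, k + 2, k + 3, k + 4)
  expect_equal(got, pv2[k] / mean(pv2[neigh]), tolerance = 1e-12)
  expect_error(snrAt(mkSpec(pv2), 7.51), "bin")
  expect_error(snrAt(mkSpec(rep(1, 5)), 0.3125), "range")
})

test_that("SNR is invariant to rescaling the time series", {
  net <- smallNet(34)
  set.seed(61)
  m <- matrix(rnorm(34 * 2250), 34)
  t1 <- seq(-600, 3898, by = 2)
  a1 <- avgFromMatrix(m, sensorIds = sensorIds(net))
  a2 <- avgFromMatrix(5.7 * m, sensorIds = sensorIds(net))
  s1 <- snrAt(computePowerSpectrum(a1), 7.5)
  s2 <- snrAt(computePowerSpectrum(a2), 7.5)
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("occipital pooling is the arithmetic mean over the 8-sensor pool", {
  net <- smallNet(34)
  snr <- matrix(3, 2, 34, dimnames = list(NULL, sensorIds(net)))
  expect_equal(unname(poolSensors(snr, net)), c(3, 3))
  snr2 <- snr
  snr2[1, occipitalPool(net)] <- 1:8
  expect_equal(unname(poolSensors(snr2, net)[1]), 4.5)
  set.seed(71)
  snr3 <- matrix(runif(34), 1, 34, dimnames = list(NULL, sensorIds(net)))
  expect_equal(unname(poolSensors(snr3, net)[1]),
               mean(snr3[1, occipitalPool(net)]))
  expect_error(poolSensors(snr3[, 1:10, drop = FALSE], net), "missing")
})
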