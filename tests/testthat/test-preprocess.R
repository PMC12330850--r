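test_that("epoch extraction matches a direct slice oracle and errors on truncation", {
  sfreq <- 500
  cont <- matrix(seq_len(3 * 5000), nrow = 3)   # ramp, unique per sample
  onsets <- c(2.0, 4.5, 5.75)
  ep <- extractEpochs(cont, onsets, sfreq)
  expect_equal(dim(ep@data), c(3L, 3L, 2250L))
  for (e in seq_along(onsets)) {
    onsetIdx <- ceiling(onsets[e] * sfreq) + 1
    oracle <- cont[, (onsetIdx - 300):(onsetIdx + 1949)]
    expect_equal(ep@data[e, , ], oracle)
  }
  expect_error(extractEpochs(cont, 9.9, sfreq), "truncated")
  expect_error(extractEpochs(cont, 0.1, sfreq), "truncated")
})

test_that("10 valid events give 10 epochs of 2250 samples at 500 Hz", {
  cont <- matrix(rnorm(2 * 40000), nrow = 2)
  ep <- extractEpochs(cont, seq(2, 70, length.out = 10), 500)
  expect_equal(dim(ep@data), c(10L, 2L, 2250L))
})

test_that("low-pass filter preserves the passband, kills the stopband, leaves DC", {
  sfreq <- 500
  t <- (0:2249) / sfreq
  mk <- function(x) epochsFromArray(array(rep(x, each = 1),
                                          dim = c(1, 1, length(x))))
  pass <- sin(2 * pi * 7.5 * t)
  f <- lowpassFilter(mk(pass))@data[1, 1, ]
  mid <- 300:1900
  expect_equal(sd(f[mid]) / sd(pass[mid]), 1, tolerance = 0.01)
  stop100 <- sin(2 * pi * 100 * t)
  g <- lowpassFilter(mk(stop100))@data[1, 1, ]
  # analytic double-pass Butterworth magnitude at 100 Hz
  H <- 1 / (1 + (100 / 40)^(2 * 4))          # |H|^2 of one pass
  expect_lt(sd(g[mid]) / sd(stop100[mid]), 10^(-40 / 20))
  expect_equal(sd(g[mid]) / sd(stop100[mid]), H, tolerance = 0.05)
  dc <- rep(2.5, 2250)
  expect_equal(lowpassFilter(mk(dc))@data[1, 1, ], dc, tolerance = 1e-6)
  expect_error(lowpassFilter(mk(pass), cutoffHz = 250), "Nyquist")
})

test_that("filtering is linear", {
  ep1 <- noiseEpochs(2, 3, seed = 11)
  ep2 <- noiseEpochs(2, 3, seed = 12)
  comb <- epochsFromArray(2 * ep1@data - 3 * ep2@data)
  lhs <- lowpassFilter(comb)@data
  rhs <- 2 * lowpassFilter(ep1)@data - 3 * lowpassFilter(ep2)@data
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("SCADS leaves clean homogeneous data essentially unflagged", {
  ep <- noiseEpochs(200, 32, nSamples = 200, seed = 5)
  rep <- scadsScreen(ep)
  # 6 two-sided robust-z tests at |z| > 3; the screening statistics are
  # right-skewed (extreme-value / chi-like), so the false-positive rate
  # sits somewhat above the Gaussian 6 x 0.27% envelope but stays small
  expect_lt(mean(rep@sensorFlags), 0.08)
  expect_gt(mean(rep@sensorFlags), 0.001)   # the threshold is not inert
  expect_length(rep@rejectedTrials, 0L)
})

test_that("a constructed spike is flagged exactly where it was injected", {
  ep <- noiseEpochs(30, 8, nSamples = 200, seed = 6)
  spec <- data.frame(trial = 17, sensor = 4, kind = "spike",
                     magnitude = 500)
  bad <- injectArtifacts(ep, spec)
  rep <- scadsScreen(bad)
  expect_true(rep@sensorFlags[17, 4])
  expect_true(rep@interpolated[17, 4])
  expect_length(rep@rejectedTrials, 0L)
})

test_that("a trial with more than maxBadSensors contaminated sensors is rejected", {
  net <- smallNet(30)
  ep <- noiseEpochs(20, 30, nSamples = 200, seed = 7)
  spec <- data.frame(trial = 9, sensor = 1:25, kind = "spike",
                     magnitude = 500)
  bad <- injectArtifacts(ep, spec)
  rep <- scadsScreen(bad, zThreshold = 3, maxBadSensors = 20L)
  expect_true(9L %in% rep@rejectedTrials)
  expect_false(any(rep@interpolated[9, ]))
  expect_error(scadsScreen(epochsFromArray(ep@data[1, , , drop = FALSE])),
               "2 trials")
})

test_that("screening flags more on artifact-laden than on clean data", {
  ep <- noiseEpochs(40, 12, nSamples = 200, seed = 8)
  spec <- data.frame(trial = sample(1:40, 10), sensor = sample(1:12, 10, TRUE),
                     kind = "spike", magnitude = 300)
  dirty <- injectArtifacts(ep, spec, seed = 2)
  expect_gt(sum(scadsScreen(dirty)@sensorFlags),
            sum(scadsScreen(ep)@sensorFlags))
})

test_that("spherical-spline interpolation is exact for constants and identity without flags", {
  net <- smallNet(34)
  nS <- length(sensorIds(net))
  dat <- array(rnorm(3 * nS * 50), dim = c(3, nS, 50))
  dat[2, , ] <- 4.2                      # spatially constant trial
  ep <- epochsFromArray(dat, sensorIds = sensorIds(net))
  flags <- matrix(FALSE, 3, nS)
  noRep <- new("ArtifactReport", sensorFlags = flags, interpolated = flags,
               rejectedTrials = integer(), stats = list(),
               params = list(maxBadSensors = 20L))
  expect_identical(interpolateSensors(ep, noRep, net)@data, ep@data)
  flags2 <- flags; flags2[2, 5] <- TRUE
  rep2 <- new("ArtifactReport", sensorFlags = flags2, interpolated = flags2,
              rejectedTrials = integer(), stats = list(),
              params = list(maxBadSensors = 20L))
  out <- interpolateSensors(ep, rep2, net)
  expect_equal(out@data[2, 5, ], rep(4.2, 50), tolerance = 1e-6)
  expect_identical(out@data[2, -5, ], ep@data[2, -5, ])  # others untouched
})

test_that("leave-one-out interpolation recovers a smooth spherical-harmonic field", {
  net <- smallNet(64)
  pos <- net@positions
  field <- sqrt(3) * pos[, 1] * pos[, 3] + 0.5 * pos[, 2]  # degree 1+2 mix
  nS <- nrow(pos)
  dat <- array(0, dim = c(1, nS, 4))
  for (k in 1:4) dat[1, , k] <- field * k
  ep <- epochsFromArray(dat, sensorIds = sensorIds(net))
  errs <- vapply(seq(2, nS, by = 7), function(drop) {
    flags <- matrix(FALSE, 1, nS); flags[1, drop] <- TRUE
    rep <- new("ArtifactReport", sensorFlags = flags, interpolated = flags,
               rejectedTrials = integer(), stats = list(),
               params = list(maxBadSensors = 20L))
    out <- interpolateSensors(ep, rep, net)
    abs(out@data[1, drop, 1] - field[drop]) /
      max(abs(field))
  }, 0)
  expect_lt(stats::median(errs), 0.05)
  expect_lt(max(errs), 0.15)
  # interpolation preserves the all-sensor mean of the zero-mean field
  fieldZ <- field - mean(field)
  datZ <- array(0, dim = c(1, nS, 1)); datZ[1, , 1] <- fieldZ
  epZ <- epochsFromArray(datZ, sensorIds = sensorIds(net))
  flags <- matrix(FALSE, 1, nS); flags[1, 11] <- TRUE
  repZ <- new("ArtifactReport", sensorFlags = flags, interpolated = flags,
              rejectedTrials = integer(), stats = list(),
              params = list(maxBadSensors = 20L))
  outZ <- interpolateSensors(epZ, repZ, net)
  expect_equal(mean(outZ@data[1, , 1]), mean(fieldZ),
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("condition averaging equals a naive loop oracle and tracks trial counts", {
  dat <- array(rnorm(12 * 4 * 20), dim = c(12, 4, 20))
  labels <- data.frame(orientation_deg = rep(c(45, -45), 6),
                       context = rep(c("aversive", "neutral"), each = 6),
                       phase = "context", half = NA_integer_)
  ep <- epochsFromArray(dat, labels = labels)
  avg <- averageConditions(ep)
  for (i in seq_len(nrow(avg@conditions))) {
    sel <- labels$orientation_deg == avg@conditions$orientation_deg[i] &
      labels$context == avg@conditions$context[i]
    oracle <- matrix(0, 4, 20)
    for (tr in which(sel)) oracle <- oracle + dat[tr, , ]
    oracle <- oracle / sum(sel)
    expect_equal(avg@data[i, , ], oracle, tolerance = 1e-12)
    expect_equal(avg@conditions$n_trials[i], sum(sel))
  }
  # +v / -v trials average to zero
  v <- array(rnorm(1 * 2 * 10), dim = c(1, 2, 10))
  pm <- array(0, dim = c(2, 2, 10)); pm[1, , ] <- v[1, , ]; pm[2, , ] <- -v[1, , ]
  ep2 <- epochsFromArray(pm)
  expect_equal(averageConditions(ep2)@data[1, , ], matrix(0, 2, 10),
               tolerance = 1e-12)
})

test_that("rejected trials are excluded from averages", {
  dat <- array(0, dim = c(4, 2, 5))
  dat[4, , ] <- 100
  ep <- epochsFromArray(dat)
  flags <- matrix(FALSE, 4, 2)
  rep <- new("ArtifactReport", sensorFlags = flags, interpolated = flags,
             rejectedTrials = 4L, stats = list(), params = list())
  avg <- averageConditions(ep, report = rep)
  expect_equal(avg@data[1, , ], matrix(0, 2, 5))
  expect_equal(avg@conditions$n_trials, 3L)
})

test_that("half split assigns ceiling(n/2) to the first half and applies the empty-cell rule", {
  labels <- data.frame(orientation_deg = rep(c(45, -45), length.out = 7),
                       context = "none", phase = "acquisition",
                       half = NA_integer_)
  ep <- epochsFromArray(array(rnorm(7 * 2 * 10), dim = c(7, 2, 10)),
                        labels = labels)
  sh <- splitHalvesAndScreen(ep)
  expect_equal(sum(trialLabels(sh$epochs)$half == 1L), 4L)
  expect_false(sh$participantExcluded)
  # rejecting every second-half CS+ trial empties a Cue x Half cell
  lab2 <- trialLabels(sh$epochs)
  rejIdx <- which(lab2$half == 2L & lab2$orientation_deg == 45)
  flags <- matrix(FALSE, 7, 2)
  rep <- new("ArtifactReport", sensorFlags = flags, interpolated = flags,
             rejectedTrials = as.integer(rejIdx), stats = list(),
             params = list())
  sh2 <- splitHalvesAndScreen(ep, rep)
  expect_true(sh2$participantExcluded)
})
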