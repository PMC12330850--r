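miniSched <- function(n = 4L) {
  new("TrialSchedule", records = data.frame(
    phase = "context", block_index = 1L,
    context = rep(c("aversive", "neutral"), length.out = n),
    orientation_deg = rep(c(45, -45), length.out = n),
    onset_s = 6 + (0:(n - 1)) * 6.5, duration_s = 4, isi_s = 2.5,
    reinforced = rep(c(45, -45), length.out = n) == 45))
}

test_that("noise-free fundamental-only epochs are spectrally pure", {
  net <- smallNet()
  p <- genParams(a1Base = 1, a1ContextOffset = 0, a2Base = 0,
                 a2GradientPeak = 0, noiseScale = 0, subjectSd = 0)
  ep <- generateEegEpochs(miniSched(2), p, net, subjectId = 1)
  oz <- match("E75", sensorIds(net))
  x <- ep@data[1, oz, ]
  times <- timesMs(ep)
  # cycle-aligned window: 600..3800 ms = 24 cycles of 7.5 Hz
  idx <- times >= 600 & times < 3800
  w <- x[idx] - mean(x[idx])
  pw <- Mod(fft(w))^2
  k <- round(7.5 * sum(idx) / 500) + 1
  expect_lt(1 - pw[k] * 2 / sum(pw), 1e-10)  # all power in the f0 bin pair
})

test_that("recovered spectral amplitudes match a direct-DFT oracle of the closed-form signal", {
  net <- smallNet()
  p <- genParams(a1Base = 1.3, a1ContextOffset = 0.5, a2Base = 0.7,
                 a2GradientPeak = 0.4, noiseScale = 0, subjectSd = 0)
  sched <- miniSched(4)
  ep <- generateEegEpochs(sched, p, net, subjectId = 2)
  oz <- match("E75", sensorIds(net))
  times <- timesMs(ep)
  idx <- which(times >= 0 & times < 3200)     # 24 cycles, within cue-on
  tSec <- times[idx] / 1000
  for (tr in 1:4) {
    ctx <- scheduleRecords(sched)$context[tr]
    ori <- scheduleRecords(sched)$orientation_deg[tr]
    a1 <- p@a1Base + p@a1ContextOffset * (ctx == "aversive")
    a2 <- p@a2Base + p@a2GradientPeak * orientationGradient(ori, p@a2GradientWidthDeg)
    # direct DFT of the generated samples at the two tagged frequencies
    x <- ep@data[tr, oz, idx]
    for (fr in c(7.5, 15)) {
      amp <- 2 * Mod(sum(x * exp(-2i * pi * fr * tSec))) / length(x)
      expected <- if (fr == 7.5) a1 else a2
      expect_equal(amp, expected, tolerance = 1e-9)
    }
  }
})

test_that("amplitude ordering of generated conditions follows the generating model", {
  p <- genParams()
  g <- orientationGradient(c(-45, 15, 25, 35, 45, 55, 65, 75),
                           p@a2GradientWidthDeg)
  expect_equal(which.max(g), 5L)            # CS+ peak
  expect_true(all(diff(g[2:5]) > 0) && all(diff(g[5:8]) < 0))
})

test_that("epoch generation is deterministic per (seed, subject) and varies by subject", {
  net <- smallNet()
  p <- genParams(noiseScale = 3, trialsPerCell = 6L)
  s <- miniSched(2)
  a <- generateEegEpochs(s, p, net, subjectId = 1)
  b <- generateEegEpochs(s, p, net, subjectId = 1)
  c <- generateEegEpochs(s, p, net, subjectId = 2)
  expect_identical(a@data, b@data)
  expect_false(identical(a@data, c@data))
})

test_that("topography peaks at Oz and decays with angular distance", {
  net <- smallNet(129)
  topo <- occipitalTopography(net)
  names(topo) <- sensorIds(net)
  expect_equal(names(which.max(topo)), "E75")
  expect_true(all(topo[occipitalPool(net)] >
                    stats::quantile(topo, 0.75)))
})

test_that("artifact injection is identity for an empty spec and errors out of range", {
  ep <- noiseEpochs(4, 6)
  empty <- data.frame(trial = integer(), sensor = integer(),
                      kind = character(), magnitude = numeric())
  expect_identical(injectArtifacts(ep, empty)@data, ep@data)
  bad <- data.frame(trial = 99, sensor = 1, kind = "spike", magnitude = 10)
  expect_error(injectArtifacts(ep, bad), "out-of-range")
})

test_that("pupil generator: no blinks means no missing samples; null model is flat", {
  p0 <- genParams(blinkRateHz = 0, pupilGainMm = 0,
                  pupilContextOffsetMm = 0, pupilNoiseSd = 0.01)
  tr <- generatePupil(miniSched(6), p0, subjectId = 1)
  expect_false(any(is.na(values(tr))))
  resp <- meanResponse(baselineCorrect(tr))
  expect_true(all(abs(resp) < 0.02))        # noise-level only
  pB <- genParams(blinkRateHz = 0.5)
  trB <- generatePupil(miniSched(6), pB, subjectId = 1)
  expect_true(any(is.na(values(trB))))
})

test_that("noise-free pupil means reproduce the closed-form gradient", {
  p <- genParams(blinkRateHz = 0, pupilNoiseSd = 0)
  sched <- generateSchedule("context", seed = 5, trialsPerCell = 6L)
  tr <- generatePupil(sched, p, subjectId = 3)
  resp <- meanResponse(baselineCorrect(tr))
  lab <- trialLabels(tr)
  # closed-form oracle: amplitude x window-mean of the response shape
  shape <- pupilResponseShape(timesMs(tr))
  win <- timesMs(tr) >= 500 & timesMs(tr) <= 4000
  base <- timesMs(tr) >= -500 & timesMs(tr) < 0
  shapeMean <- mean(shape[win]) - mean(shape[base])
  expAmp <- p@pupilGainMm *
    orientationGradient(lab$orientation_deg, p@a2GradientWidthDeg) +
    p@pupilContextOffsetMm * (lab$context == "aversive")
  expect_equal(resp, expAmp * shapeMean, tolerance = 1e-9)
})

test_that("rating tables follow the clipped-normal model", {
  # degenerate: no noise, no offsets, flat gradient -> all equal
  pf <- genParams(ratingNoiseSd = 0, ratingSubjectSd = 0,
                  ratingContextOffset = 0, ratingGradient = 0)
  r0 <- generateRatings(pf, nSubjects = 4, seed = 2)
  expect_true(all(r0$rating == r0$rating[1]))
  # context offset raises the aversive mean
  p <- genParams()
  r <- generateRatings(p, nSubjects = 120, seed = 3)
  expect_gt(mean(r$rating[r$context == "aversive"]),
            mean(r$rating[r$context == "neutral"]))
  # grand mean matches the analytic mean of the clipped normal
  pc <- genParams(ratingFloor = 90, ratingGradient = 30,
                  ratingContextOffset = 0, ratingSubjectSd = 8,
                  ratingNoiseSd = 12)   # heavy clipping at 100
  big <- generateRatings(pc, nSubjects = 400, seed = 4)
  cs <- big[big$orientation_deg == 45, ]
  mu <- 120; sig <- sqrt(8^2 + 12^2)
  a <- (0 - mu) / sig; b <- (100 - mu) / sig
  anaMean <- mu + sig * (dnorm(a) - dnorm(b)) +
    (0 - mu) * pnorm(a) + (100 - mu) * (1 - pnorm(b))
  expect_equal(mean(cs$rating), anaMean, tolerance = 0.02)
})

test_that("generator determinism extends to pupil and ratings", {
  p <- genParams()
  s <- miniSched(3)
  expect_identical(values(generatePupil(s, p, 1)),
                   values(generatePupil(s, p, 1)))
  expect_identical(generateRatings(p, 6, seed = 9),
                   generateRatings(p, 6, seed = 9))
})
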