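# shared fixtures: tiny sensor nets and epoch builders, constructed in code

smallNet <- function(n = 34L) egiSensorNet(n)

# epochs holding an arbitrary (trials x sensors x samples) array with a
# valid time axis
epochsFromArray <- function(dat, sfreq = 500,
                            startMs = -600,
                            labels = NULL, sensorIds = NULL) {
  d <- dim(dat)
  if (is.null(sensorIds)) sensorIds <- paste0("E", seq_len(d[2]))
  if (is.null(labels))
    labels <- data.frame(orientation_deg = rep(45, d[1]),
                         context = "none", phase = "acquisition",
                         half = NA_integer_)
  times <- startMs + (seq_len(d[3]) - 1L) * 1000 / sfreq
  new("EpochArray", data = dat, sfreq = sfreq, timesMs = times,
      labels = labels, sensorIds = sensorIds)
}

# noise-only epochs for screening tests
noiseEpochs <- function(nTrials, nSensors, nSamples = 300, sd = 1,
                        seed = 1) {
  set.seed(seed)
  epochsFromArray(array(rnorm(nTrials * nSensors * nSamples, 0, sd),
                        dim = c(nTrials, nSensors, nSamples)))
}

# single-condition ConditionAverage wrapping a sensors x samples matrix
avgFromMatrix <- function(m, sfreq = 500, startMs = -600,
                          sensorIds = NULL) {
  if (is.null(sensorIds)) sensorIds <- paste0("E", seq_len(nrow(m)))
  arr <- array(0, dim = c(1, nrow(m), ncol(m)))
  arr[1, , ] <- m
  times <- startMs + (seq_len(ncol(m)) - 1L) * 1000 / sfreq
  new("ConditionAverage", data = arr,
      conditions = data.frame(orientation_deg = 45, context = "none",
                              n_trials = 1L),
      sfreq = sfreq, timesMs = times, sensorIds = sensorIds, units = "uV")
}

# pupil trace set from a trials x samples matrix at 60 Hz
pupilFromMatrix <- function(m, startMs = -500, labels = NULL) {
  if (is.null(labels))
    labels <- data.frame(orientation_deg = rep(45, nrow(m)),
                         context = "none", phase = "context")
  times <- startMs + (seq_len(ncol(m)) - 1L) * 1000 / 60
  new("PupilTraceSet", traces = m, missingMask = is.na(m),
      timesMs = times, sfreq = 60, labels = labels)
}
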