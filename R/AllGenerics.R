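#' @rdname SensorNet-class
#' @param object,x an object.
#' @export
setGeneric("sensorIds", function(x) standardGeneric("sensorIds"))

#' @rdname SensorNet-class
#' @export
setGeneric("sensorPositions", function(x) standardGeneric("sensorPositions"))

#' @rdname SensorNet-class
#' @export
setGeneric("occipitalPool", function(x) standardGeneric("occipitalPool"))

#' @rdname TrialSchedule-class
#' @param x an object.
#' @export
setGeneric("scheduleRecords", function(x) standardGeneric("scheduleRecords"))

#' Number of trials in a container
#' @param x an EpochArray, PupilTraceSet or TrialSchedule.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Per-trial condition labels
#' @param x an EpochArray or PupilTraceSet.
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' Epoch / trace time axis in ms relative to cue onset
#' @param x an EpochArray, ConditionAverage or PupilTraceSet.
#' @export
setGeneric("timesMs", function(x) standardGeneric("timesMs"))

#' Numeric payload of a container
#' @param x an EpochArray, ConditionAverage, PowerSpectrum or PupilTraceSet.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Effects table of an AnovaResult
#' @param x an AnovaResult.
#' @export
setGeneric("effects", function(x) standardGeneric("effects"))

#' Topography table of a BFMap
#' @param x a BFMap.
#' @export
setGeneric("bfTable", function(x) standardGeneric("bfTable"))

setMethod("sensorIds", "SensorNet", function(x) x@sensorIds)
setMethod("sensorIds", "EpochArray", function(x) x@sensorIds)
setMethod("sensorIds", "ConditionAverage", function(x) x@sensorIds)
setMethod("sensorIds", "PowerSpectrum", function(x) x@sensorIds)
setMethod("sensorPositions", "SensorNet", function(x) {
  p <- x@positions
  rownames(p) <- x@sensorIds
  p
})
setMethod("occipitalPool", "SensorNet", function(x) x@occipitalPool)
setMethod("scheduleRecords", "TrialSchedule", function(x) x@records)
setMethod("nTrials", "TrialSchedule", function(x) nrow(x@records))
setMethod("nTrials", "EpochArray", function(x) dim(x@data)[1])
setMethod("nTrials", "PupilTraceSet", function(x) nrow(x@traces))
setMethod("trialLabels", "EpochArray", function(x) x@labels)
setMethod("trialLabels", "PupilTraceSet", function(x) x@labels)
setMethod("timesMs", "EpochArray", function(x) x@timesMs)
setMethod("timesMs", "ConditionAverage", function(x) x@timesMs)
setMethod("timesMs", "PupilTraceSet", function(x) x@timesMs)
setMethod("values", "EpochArray", function(x) x@data)
setMethod("values", "ConditionAverage", function(x) x@data)
setMethod("values", "PowerSpectrum", function(x) x@power)
setMethod("values", "PupilTraceSet", function(x) x@traces)
setMethod("effects", "AnovaResult", function(x) x@effects)
setMethod("bfTable", "BFMap", function(x) x@map)

setMethod("show", "SensorNet", function(object) {
  cat("SensorNet with", length(object@sensorIds), "sensors\n")
  cat("  occipital pool:", paste(object@occipitalPool, collapse = " "), "\n")
})

setMethod("show", "TrialSchedule", function(object) {
  rec <- object@records
  cat("TrialSchedule:", nrow(rec), "trials,",
      length(unique(rec$block_index)), "block(s), phase:",
      paste(unique(rec$phase), collapse = "/"), "\n")
  tab <- table(rec$orientation_deg, rec$context)
  print(tab)
})

setMethod("show", "EpochArray", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochArray: %d trials x %d sensors x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@sfreq))
  cat(sprintf("  window %g..%g ms relative to cue onset\n",
              min(object@timesMs), max(object@timesMs)))
})

setMethod("show", "ConditionAverage", function(object) {
  d <- dim(object@data)
  cat(sprintf("ConditionAverage (%s): %d conditions x %d sensors x %d samples\n",
              object@units, d[1], d[2], d[3]))
})

setMethod("show", "PowerSpectrum", function(object) {
  d <- dim(object@power)
  cat(sprintf("PowerSpectrum: %d conditions x %d sensors x %d bins (%.4g Hz resolution)\n",
              d[1], d[2], d[3], object@binWidthHz))
})

setMethod("show", "PupilTraceSet", function(object) {
  cat(sprintf("PupilTraceSet: %d trials x %d samples @ %g Hz; %.1f%% samples missing\n",
              nrow(object@traces), ncol(object@traces), object@sfreq,
              100 * mean(object@missingMask)))
})

setMethod("show", "ArtifactReport", function(object) {
  cat(sprintf("ArtifactReport: %d/%d trials rejected; %.2f%% sensor-trials flagged\n",
              length(object@rejectedTrials), nrow(object@sensorFlags),
              100 * mean(object@sensorFlags)))
})

setMethod("show", "AnovaResult", function(object) {
  eff <- object@effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("%s: F(%.2f, %.2f) = %.2f, p = %.4g, pes = %.3f [%.3f; %.3f]\n",
                eff$effect[i], eff$df1_corr[i], eff$df2_corr[i], eff$F[i],
                eff$p[i], eff$pes[i], eff$pes_lo[i], eff$pes_hi[i]))
  }
})

setMethod("show", "TTestResult", function(object) {
  cat(sprintf("t(%d) = %.2f, p = %.4g, d = %.2f, CI95 = [%.2f; %.2f]\n",
              as.integer(object@df), object@t, object@p, object@d,
              object@dLo, object@dHi))
})

setMethod("show", "WeightModel", function(object) {
  cat(sprintf("WeightModel '%s': %s\n", object@name,
              paste(sprintf("%+g", object@weights), collapse = " ")))
})

setMethod("show", "BFMap", function(object) {
  cat("BFMap:", nrow(object@map), "sensor x frequency x model cells\n")
  agg <- stats::aggregate(log_bf ~ frequency_hz + model, object@map, max)
  print(agg)
})
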