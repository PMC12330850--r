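#' Pipeline run configuration
#'
#' Collects every stage parameter with defaults reproducing the study's
#' printed settings: 7.5 Hz driving frequency, -600..+3900 ms epochs,
#' 40 Hz low-pass, SCADS screening with trial rejection above 20 bad
#' sensors, CSD with lambda = 0.2, FFT window 600-3900 ms (cycle-aligned),
#' SNR noise bins +-2..+-4, Oz + 7 occipital pooling, alpha = .05, and the
#' n = 50 / d = .30 / SD = 1.4 / rho = .80 / 5000-replicate power
#' simulation. Any field can be overridden.
#'
#' @param seed master seed fanned out to per-module substreams via
#'   \code{deriveSeed}.
#' @param nSubjects cohort size.
#' @param nSensors sensor-net size (129 = reference layout).
#' @param genParams a \linkS4class{GenParams} (constructed from nSubjects
#'   and seed when NULL).
#' @param filterCutoffHz,filterOrder EEG low-pass settings.
#' @param zThreshold,maxBadSensors SCADS settings.
#' @param csdLambda,csdM,csdTerms CSD settings.
#' @param fftWindowMs,alignHz spectral settings.
#' @param frequencies tagged frequencies analysed (Hz).
#' @param includeAcquisition run the acquisition phase (Cue x Time) as well
#'   as the context phase.
#' @param perSensorBf also compute per-sensor BF topographies (costly).
#' @param alpha significance level.
#' @param powerConfig a "powerSimConfig".
#' @param outDir optional output directory for CSVs + manifest.
#' @return a list of class "ssvepRunConfig".
#' @export
runConfig <- function(seed = 1L, nSubjects = 52L, nSensors = 129L,
                      genParams = NULL,
                      filterCutoffHz = 40, filterOrder = 4,
                      zThreshold = 3, maxBadSensors = 20L,
                      csdLambda = 0.2, csdM = 4, csdTerms = 50,
                      fftWindowMs = c(600, 3900), alignHz = 7.5,
                      frequencies = c(7.5, 15),
                      includeAcquisition = TRUE, perSensorBf = FALSE,
                      alpha = 0.05,
                      powerConfig = powerSimConfig(seed = seed),
                      outDir = NULL) {
  if (is.null(genParams))
    genParams <- ssvepContext::genParams(nSubjects = nSubjects, seed = seed)
  structure(list(seed = as.integer(seed), nSubjects = as.integer(nSubjects),
                 nSensors = as.integer(nSensors), genParams = genParams,
                 filterCutoffHz = filterCutoffHz, filterOrder = filterOrder,
                 zThreshold = zThreshold,
                 maxBadSensors = as.integer(maxBadSensors),
                 csdLambda = csdLambda, csdM = csdM, csdTerms = csdTerms,
                 fftWindowMs = fftWindowMs, alignHz = alignHz,
                 frequencies = frequencies,
                 includeAcquisition = includeAcquisition,
                 perSensorBf = perSensorBf, alpha = alpha,
                 powerConfig = powerConfig, outDir = outDir),
            class = "ssvepRunConfig")
}

#' Serialize / restore a run configuration as YAML
#'
#' The GenParams and power blocks are flattened to named scalar fields so
#' the round trip is lossless.
#'
#' @param config an "ssvepRunConfig".
#' @param path YAML file path.
#' @return \code{readRunConfigYaml} returns the reconstructed config.
#' @export
writeRunConfigYaml <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for YAML serialization")
  gp <- config$genParams
  gpList <- sapply(slotNames(gp), function(s) slot(gp, s),
                   simplify = FALSE)
  out <- config[setdiff(names(config), c("genParams", "powerConfig"))]
  out$genParams <- gpList
  out$powerConfig <- unclass(config$powerConfig)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname writeRunConfigYaml
#' @export
readRunConfigYaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for YAML serialization")
  raw <- yaml::read_yaml(path)
  gp <- do.call(genParams, raw$genParams)
  pc <- do.call(powerSimConfig, raw$powerConfig)
  args <- raw[setdiff(names(raw), c("genParams", "powerConfig"))]
  args$genParams <- gp
  args$powerConfig <- pc
  args$fftWindowMs <- as.numeric(args$fftWindowMs)
  args$frequencies <- as.numeric(args$frequencies)
  do.call(runConfig, args)
}

#' Process one subject's epochs into SNR rows
#'
#' filter -> SCADS screen -> spherical-spline interpolation -> condition
#' averaging -> CSD -> cycle-aligned FFT -> neighbour-bin SNR at the tagged
#' frequencies, pooled over the occipital cluster (per-sensor rows
#' optional).
#'
#' @param epochs a raw EpochArray.
#' @param net the matching SensorNet.
#' @param config an "ssvepRunConfig".
#' @param subjectId subject index for the output rows.
#' @param grouping condition label columns.
#' @param perSensor also emit per-sensor SNR rows.
#' @return list(snr = data.frame rows, retainedFraction, report,
#'   conditions).
#' @export
processSubjectEeg <- function(epochs, net, config, subjectId,
                              grouping = c("orientation_deg", "context"),
                              perSensor = config$perSensorBf) {
  filt <- lowpassFilter(epochs, config$filterCutoffHz, config$filterOrder)
  rep <- scadsScreen(filt, net, config$zThreshold, config$maxBadSensors)
  clean <- interpolateSensors(filt, rep, net)
  avg <- averageConditions(clean, grouping = grouping, report = rep)
  csd <- csdTransform(avg, net, lambda = config$csdLambda, m = config$csdM,
                      nTerms = config$csdTerms)
  spec <- computePowerSpectrum(csd, windowMs = config$fftWindowMs,
                               alignCyclesToHz = config$alignHz)
  conds <- spec@conditions
  rows <- list()
  for (f in config$frequencies) {
    snrMat <- snrAt(spec, f)
    pooled <- poolSensors(snrMat, net)
    base <- conds[setdiff(names(conds), "n_trials")]
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(subject = subjectId), base,
      data.frame(frequency_hz = f, sensor = "pooled", pooled = TRUE,
                 snr = unname(pooled)))
    if (perSensor) {
      for (s in seq_along(spec@sensorIds)) {
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(subject = subjectId), base,
          data.frame(frequency_hz = f, sensor = spec@sensorIds[s],
                     pooled = FALSE, snr = unname(snrMat[, s])))
      }
    }
  }
  retained <- 1 - length(rep@rejectedTrials) / nTrials(epochs)
  list(snr = do.call(rbind, rows), retainedFraction = retained,
       report = rep, conditions = conds)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' generate -> preprocess -> CSD/spectral -> pupil -> ratings -> rmANOVA /
#' t-tests -> JZS Bayes factors -> power simulation, fully deterministic
#' given the config seed. Returns a structured report and (optionally)
#' writes tidy CSVs plus a JSON manifest to \code{config$outDir}.
#'
#' @param config an "ssvepRunConfig".
#' @param verbose log stage progress to stderr.
#' @return a list of class "ssvepRunReport" with blocks: snr (SNRTable),
#'   ratings, pupil, anova (per measure/frequency), ttests, bayes, power,
#'   exclusions, manifest.
#' @export
runPipeline <- function(config = runConfig(), verbose = TRUE) {
  stopifnot(inherits(config, "ssvepRunConfig"))
  log_ <- function(...) if (verbose) message("[ssvepContext] ", ...)
  params <- config$genParams
  net <- egiSensorNet(config$nSensors)
  nSubj <- config$nSubjects

  ## ratings ----
  log_("ratings: generating and testing (n = ", nSubj, ")")
  ratCtx <- generateRatings(params, nSubj, seed = config$seed)
  ratingAnova <- rmAnova(ratCtx, "rating", c("orientation_deg", "context"),
                         "subject")
  ratAcq <- generateRatings(params, nSubj, seed = config$seed,
                            phase = "acquisition")
  ratingAcqAnova <- rmAnova(ratAcq, "rating", "orientation_deg", "subject")
  ratingT <- pairedCsContrast(ratAcq, "rating")

  ## pupil ----
  log_("pupil: per-subject traces and condition means")
  pupilTab <- do.call(rbind, lapply(seq_len(nSubj), function(s) {
    sched <- generateSchedule("context",
                              seed = deriveSeed(config$seed, "sched-ctx", s),
                              trialsPerCell = params@trialsPerCell)
    cm <- pupilConditionMeans(generatePupil(sched, params, s))
    cbind(subject = s, cm)
  }))
  pupilAnova <- rmAnova(pupilTab, "response_mm",
                        c("orientation_deg", "context"), "subject")
  pupilT <- pairedCsContrast(pupilTab, "response_mm")

  ## EEG: context phase ----
  log_("eeg: context phase, ", nSubj, " subjects x ",
       config$nSensors, " sensors")
  snrRows <- list(); retained <- numeric(nSubj)
  for (s in seq_len(nSubj)) {
    sched <- generateSchedule("context",
                              seed = deriveSeed(config$seed, "sched-ctx", s),
                              trialsPerCell = params@trialsPerCell)
    ep <- generateEegEpochs(sched, params, net, s)
    pr <- processSubjectEeg(ep, net, config, s)
    snrRows[[s]] <- pr$snr
    retained[s] <- pr$retainedFraction
    log_("  subject ", s, ": retained ",
         sprintf("%.1f%%", 100 * pr$retainedFraction))
  }
  snrTable <- do.call(rbind, snrRows)
  pooledSnr <- snrTable[snrTable$sensor == "pooled", ]

  eegAnova <- list(); eegT <- list()
  for (f in config$frequencies) {
    sub <- pooledSnr[pooledSnr$frequency_hz == f, ]
    key <- paste0(f, "Hz")
    eegAnova[[key]] <- rmAnova(sub, "snr", c("orientation_deg", "context"),
                               "subject")
    eegT[[key]] <- pairedCsContrast(sub, "snr")
  }

  ## EEG: acquisition phase (Cue x Time) ----
  acqBlock <- NULL
  if (config$includeAcquisition) {
    log_("eeg: acquisition phase (Cue x Time half split)")
    acqRows <- list(); excluded <- logical(nSubj)
    for (s in seq_len(nSubj)) {
      sched <- generateSchedule("acquisition",
                                seed = deriveSeed(config$seed, "sched-acq", s),
                                trialsPerCell = params@trialsPerCell)
      ep <- generateEegEpochs(sched, params, net, s)
      filt <- lowpassFilter(ep, config$filterCutoffHz, config$filterOrder)
      rep <- scadsScreen(filt, net, config$zThreshold, config$maxBadSensors)
      sh <- splitHalvesAndScreen(filt, rep)
      excluded[s] <- sh$participantExcluded
      if (sh$participantExcluded) next
      clean <- interpolateSensors(sh$epochs, rep, net)
      pr <- processSubjectEeg2(clean, rep, net, config, s,
                               grouping = c("orientation_deg", "half"))
      acqRows[[s]] <- pr
    }
    acqTab <- do.call(rbind, acqRows)
    acqAnova <- list()
    nRetained <- length(unique(acqTab$subject))
    if (nRetained >= 3L) {
      for (f in config$frequencies) {
        sub <- acqTab[acqTab$frequency_hz == f & acqTab$sensor == "pooled", ]
        acqAnova[[paste0(f, "Hz")]] <-
          rmAnova(sub, "snr", c("orientation_deg", "half"), "subject")
      }
    } else {
      log_("acquisition: only ", nRetained,
           " subject(s) retained after the empty-cell rule; Cue x Time ",
           "ANOVA skipped")
    }
    acqBlock <- list(snr = acqTab, anova = acqAnova,
                     excludedSubjects = which(excluded))
  }

  ## Bayes factors on pooled SNR ----
  log_("bayes: JZS weight models on pooled SNR")
  pooled2 <- pooledSnr
  bayesPooled <- bfTopography(pooled2, frequencies = config$frequencies)
  bayesSensor <- NULL
  if (config$perSensorBf) {
    log_("bayes: per-sensor topography")
    bayesSensor <- bfTopography(snrTable[snrTable$sensor != "pooled", ],
                                frequencies = config$frequencies)
  }

  ## power simulation ----
  log_("power: Monte-Carlo simulation")
  power <- simulatePower(config$powerConfig)

  report <- structure(list(
    snr = snrTable, ratings = list(context = ratCtx, acquisition = ratAcq),
    pupil = pupilTab,
    anova = c(list(ratings = ratingAnova, ratingsAcquisition = ratingAcqAnova,
                   pupil = pupilAnova), lapply(eegAnova, identity)),
    ttests = list(ratings = ratingT, pupil = pupilT, snr = eegT),
    bayes = list(pooled = bayesPooled, sensor = bayesSensor),
    acquisition = acqBlock,
    power = power,
    exclusions = list(retainedFraction = retained),
    config = config), class = "ssvepRunReport")
  if (!is.null(config$outDir)) writeRunReport(report, config$outDir)
  report
}

# pooled-SNR rows for pre-averaged (already screened/interpolated) epochs
processSubjectEeg2 <- function(clean, rep, net, config, subjectId, grouping) {
  avg <- averageConditions(clean, grouping = grouping, report = rep)
  csd <- csdTransform(avg, net, lambda = config$csdLambda, m = config$csdM,
                      nTerms = config$csdTerms)
  spec <- computePowerSpectrum(csd, windowMs = config$fftWindowMs,
                               alignCyclesToHz = config$alignHz)
  conds <- spec@conditions
  rows <- list()
  for (f in config$frequencies) {
    pooled <- poolSensors(snrAt(spec, f), net)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(subject = subjectId),
      conds[setdiff(names(conds), "n_trials")],
      data.frame(frequency_hz = f, sensor = "pooled", pooled = TRUE,
                 snr = unname(pooled)))
  }
  do.call(rbind, rows)
}

# CS+ vs CS-45 paired contrast on subject-level values (averaged over any
# remaining grouping columns)
pairedCsContrast <- function(tab, dv) {
  agg <- stats::aggregate(tab[[dv]],
                          list(subject = tab$subject,
                               orientation_deg = tab$orientation_deg), mean)
  cs <- agg$x[agg$orientation_deg == CS_PLUS_DEG][order(
    agg$subject[agg$orientation_deg == CS_PLUS_DEG])]
  op <- agg$x[agg$orientation_deg == -45][order(
    agg$subject[agg$orientation_deg == -45])]
  pairedT(cs, op)
}

#' Write a run report as tidy CSVs plus a JSON manifest
#'
#' @param report an "ssvepRunReport".
#' @param outDir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeRunReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, name)
  }
  wr(report$snr, "snr_table.csv")
  wr(report$ratings$context, "ratings_context.csv")
  wr(report$ratings$acquisition, "ratings_acquisition.csv")
  wr(report$pupil, "pupil_condition_means.csv")
  anovaTab <- do.call(rbind, lapply(names(report$anova), function(k) {
    cbind(measure = k, effects(report$anova[[k]]))
  }))
  wr(anovaTab, "anova_results.csv")
  wr(bfTable(report$bayes$pooled), "bf_pooled.csv")
  if (!is.null(report$bayes$sensor))
    wr(bfTable(report$bayes$sensor), "bf_topography.csv")
  bfPooled <- bfTable(report$bayes$pooled)
  bfMax <- stats::aggregate(log_bf ~ frequency_hz + model, bfPooled, max)
  manifest <- list(
    seed = report$config$seed, nSubjects = report$config$nSubjects,
    files = files,
    power = list(proportion = report$power$proportion,
                 analytic = report$power$analytic),
    meanRetainedFraction = mean(report$exclusions$retainedFraction),
    pooledLogBfMax = bfMax)
  mp <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' @export
print.ssvepRunReport <- function(x, ...) {
  cat("ssvepContext run report (seed ", x$config$seed, ", n = ",
      x$config$nSubjects, ")\n", sep = "")
  cat("mean retained-trial fraction: ",
      sprintf("%.1f%%", 100 * mean(x$exclusions$retainedFraction)), "\n",
      sep = "")
  for (k in names(x$anova)) {
    cat("\n== rmANOVA: ", k, " ==\n", sep = "")
    show(x$anova[[k]])
  }
  cat("\n== JZS log BF (pooled occipital SNR) ==\n")
  print(bfTable(x$bayes$pooled))
  cat(sprintf("\npower simulation: %.3f significant (analytic %.3f)\n",
              x$power$proportion, x$power$analytic))
  invisible(x)
}
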