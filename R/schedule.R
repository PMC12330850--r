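#' Generate a pseudo-randomized trial schedule
#'
#' Emulates the conditioning design: eight cue orientations (-45, +15, ...,
#' +75 deg; CS+ = +45 deg), 4-s cue presentations separated by 2-3 s ISIs,
#' 100 percent reinforcement of the CS+. The acquisition phase presents each
#' orientation \code{trialsPerCell} times (18 by default) in one continuous
#' run; the context phase presents 24 cues in each of six aversive and six
#' neutral blocks (3 per orientation per block), yielding 18 presentations
#' per orientation x context cell at the default. Trial order is
#' pseudo-randomized so that no more than three identical orientations occur
#' consecutively, enforced by rejection-resampling of permutations (the
#' run-length scan spans block boundaries); if a conforming order is not
#' found within \code{maxAttempts} resamples an error is raised rather than
#' silently relaxing the constraint. Block lead-in (first cue 5-7 s after
#' block start) and ISIs are drawn uniformly from the printed ranges.
#'
#' @param phase "acquisition" or "context".
#' @param seed integer; the schedule is deterministic given the seed.
#' @param trialsPerCell presentations per orientation (x context) cell;
#'   default 18. For the context phase this must be a multiple of 6 so each
#'   block holds trialsPerCell/6 cues of every orientation.
#' @param maxAttempts bound on rejection resampling per sequence.
#' @return a \linkS4class{TrialSchedule}.
#' @examples
#' sched <- generateSchedule("context", seed = 1)
#' table(scheduleRecords(sched)$orientation_deg,
#'       scheduleRecords(sched)$context)
#' @export
generateSchedule <- function(phase = c("acquisition", "context"), seed,
                             trialsPerCell = 18L, maxAttempts = 1000L) {
  phase <- match.arg(phase)
  trialsPerCell <- as.integer(trialsPerCell)
  withSeed(deriveSeed(seed, paste0("schedule-", phase)), {
    if (phase == "acquisition") {
      ords <- resampleOrder(rep(CUE_ORIENTATIONS, trialsPerCell),
                            carry = numeric(0), maxAttempts)
      rec <- scheduleBlock(ords, phase = "acquisition", blockIndex = 1L,
                           context = "none")
    } else {
      if (trialsPerCell %% 6L != 0L)
        stop("context phase needs trialsPerCell divisible by 6 (blocks)")
      perBlock <- trialsPerCell %/% 6L
      ctxOrder <- sample(rep(c("aversive", "neutral"), each = 6L))
      carry <- numeric(0)
      recs <- vector("list", 12L)
      for (b in seq_len(12L)) {
        ords <- resampleOrder(rep(CUE_ORIENTATIONS, perBlock), carry,
                              maxAttempts)
        recs[[b]] <- scheduleBlock(ords, phase = "context", blockIndex = b,
                                   context = ctxOrder[b])
        nc <- length(ords)
        carry <- ords[max(1L, nc - 2L):nc]
        run <- rle(carry)
        carry <- rep(run$values[length(run$values)],
                     run$lengths[length(run$lengths)])
      }
      rec <- do.call(rbind, recs)
    }
    new("TrialSchedule", records = rec)
  })
}

# one block's records: onsets from uniform lead-in + cue duration + ISIs
scheduleBlock <- function(orients, phase, blockIndex, context,
                          durationS = 4, leadRange = c(5, 7),
                          isiRange = c(2, 3)) {
  n <- length(orients)
  lead <- stats::runif(1, leadRange[1], leadRange[2])
  isi <- stats::runif(n, isiRange[1], isiRange[2])
  onsets <- lead + cumsum(c(0, (durationS + isi)[-n]))
  data.frame(phase = phase, block_index = blockIndex, context = context,
             orientation_deg = orients, onset_s = onsets,
             duration_s = durationS, isi_s = isi,
             reinforced = orients == CS_PLUS_DEG)
}

# rejection-resample a permutation until no orientation run exceeds 3,
# counting a carry-in run from the preceding block
resampleOrder <- function(pool, carry, maxAttempts) {
  for (att in seq_len(maxAttempts)) {
    cand <- sample(pool)
    if (maxRunLength(c(carry, cand)) <= 3L) return(cand)
  }
  stop("could not satisfy the run-length <= 3 constraint within ",
       maxAttempts, " resampling attempts")
}

#' Longest run of identical consecutive orientations
#' @param x a vector (or a TrialSchedule, scanned in record order).
#' @return integer run length.
#' @export
maxRunLength <- function(x) {
  if (is(x, "TrialSchedule")) x <- x@records$orientation_deg
  if (!length(x)) return(0L)
  max(rle(as.vector(x))$lengths)
}

#' Write / read a trial schedule as TSV
#' @param schedule a TrialSchedule.
#' @param path file path.
#' @export
writeScheduleTsv <- function(schedule, path) {
  utils::write.table(schedule@records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeScheduleTsv
#' @export
readScheduleTsv <- function(path) {
  rec <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  new("TrialSchedule", records = rec)
}
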