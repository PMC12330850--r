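#' Generate a US-expectancy rating table
#'
#' Subject x orientation x context ratings on the 0-100 scale:
#' \code{ratingFloor + ratingGradient * gradient(orientation) +
#' ratingContextOffset * [aversive] + subject intercept + noise}, clipped to
#' [0, 100]. With \code{phase = "acquisition"} a single rating per subject
#' and orientation is produced (context "none", no context offset), as
#' collected once after the acquisition phase.
#'
#' @param params a GenParams.
#' @param nSubjects number of subjects (defaults to params@nSubjects).
#' @param seed integer seed (defaults to params@seed).
#' @param phase "context" or "acquisition".
#' @return data.frame with columns subject, orientation_deg, context, rating.
#' @examples
#' head(generateRatings(genParams(nSubjects = 4), seed = 1))
#' @export
generateRatings <- function(params, nSubjects = params@nSubjects,
                            seed = params@seed,
                            phase = c("context", "acquisition")) {
  phase <- match.arg(phase)
  nSubjects <- as.integer(nSubjects)
  if (nSubjects < 2L) stop("nSubjects must be >= 2")
  contexts <- if (phase == "context") c("aversive", "neutral") else "none"
  grid <- expand.grid(subject = seq_len(nSubjects),
                      orientation_deg = CUE_ORIENTATIONS,
                      context = contexts, stringsAsFactors = FALSE)
  withSeed(deriveSeed(seed, paste0("ratings-", phase)), {
    subjInt <- stats::rnorm(nSubjects, 0, params@ratingSubjectSd)
    grad <- orientationGradient(grid$orientation_deg,
                                params@a2GradientWidthDeg)
    mu <- params@ratingFloor + params@ratingGradient * grad +
      params@ratingContextOffset * (grid$context == "aversive") +
      subjInt[grid$subject]
    val <- mu + stats::rnorm(nrow(grid), 0, params@ratingNoiseSd)
    grid$rating <- pmin(100, pmax(0, val))
    grid
  })
}

#' Write / read a rating table as TSV
#' @param ratings a rating data.frame from \code{generateRatings}.
#' @param path file path.
#' @export
writeRatingsTsv <- function(ratings, path) {
  utils::write.table(ratings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeRatingsTsv
#' @export
readRatingsTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
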