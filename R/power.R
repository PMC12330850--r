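#' Configuration of the repeated-measures power simulation
#'
#' Defaults reproduce the pre-registered sample-size simulation: n = 50
#' subjects, a raw-scale standardized mean difference d = 0.30 between the
#' two context conditions, response SD = 1.4, between-condition correlation
#' rho = 0.80, 5000 replicates, alpha = .05. d scales the raw response
#' means (delta = d * sd) with correlated measures; it is not a
#' difference-score dz.
#'
#' @param nSubjects subjects per replicate.
#' @param effectD standardized mean difference on the raw response scale.
#' @param sd common response SD.
#' @param rho correlation between the paired measures.
#' @param reps Monte-Carlo replicates.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return a validated list of class "powerSimConfig".
#' @export
powerSimConfig <- function(nSubjects = 50L, effectD = 0.30, sd = 1.4,
                           rho = 0.80, reps = 5000L, alpha = 0.05,
                           seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, abs(rho) < 1, reps >= 1, sd > 0,
            nSubjects >= 2)
  structure(list(nSubjects = as.integer(nSubjects), effectD = effectD,
                 sd = sd, rho = rho, reps = as.integer(reps),
                 alpha = alpha, seed = as.integer(seed)),
            class = "powerSimConfig")
}

#' Monte-Carlo power of the context main effect
#'
#' Per replicate draws \code{nSubjects} bivariate-normal pairs with means
#' (0, d * sd), common SD and correlation rho, and tests the context main
#' effect with a paired t-test (equivalent to the 2-level repeated-measures
#' F). Returns the fraction of replicates significant at alpha, its
#' binomial standard error, and the closed-form noncentral-t power for
#' comparison.
#'
#' @param config a "powerSimConfig".
#' @return list(proportion, se, analytic, config).
#' @examples
#' simulatePower(powerSimConfig(reps = 500))
#' @export
simulatePower <- function(config = powerSimConfig()) {
  stopifnot(inherits(config, "powerSimConfig"))
  n <- config$nSubjects
  withSeed(deriveSeed(config$seed, "power"), {
    mu <- c(0, config$effectD * config$sd)
    # bivariate pairs via common + unique components
    common <- matrix(stats::rnorm(n * config$reps), n)
    u1 <- matrix(stats::rnorm(n * config$reps), n)
    u2 <- matrix(stats::rnorm(n * config$reps), n)
    a <- sqrt(config$rho); b <- sqrt(1 - config$rho)
    x1 <- mu[1] + config$sd * (a * common + b * u1)
    x2 <- mu[2] + config$sd * (a * common + b * u2)
    d <- x2 - x1
    tStat <- colMeans(d) / (apply(d, 2, stats::sd) / sqrt(n))
    pVals <- 2 * stats::pt(abs(tStat), n - 1, lower.tail = FALSE)
    prop <- mean(pVals < config$alpha)
    list(proportion = prop,
         se = sqrt(prop * (1 - prop) / config$reps),
         analytic = analyticPairedPower(config),
         config = config)
  })
}

#' Closed-form paired-t power under the simulation model
#'
#' The paired differences have mean d * sd and SD sd * sqrt(2 (1 - rho)),
#' giving dz = d / sqrt(2 (1 - rho)) and noncentrality dz * sqrt(n); power
#' is the two-sided noncentral-t tail mass beyond the alpha critical
#' values.
#'
#' @param config a "powerSimConfig".
#' @return the analytic power.
#' @export
analyticPairedPower <- function(config) {
  n <- config$nSubjects
  dz <- config$effectD / sqrt(2 * (1 - config$rho))
  ncp <- dz * sqrt(n)
  tcrit <- stats::qt(1 - config$alpha / 2, n - 1)
  stats::pt(tcrit, n - 1, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, n - 1, ncp = ncp)
}
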