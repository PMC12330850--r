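#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject ANOVA for one or two factors, computed from the
#' subject-cell sums-of-squares decomposition. Each effect is tested against
#' its own subject-by-effect interaction error term. Sphericity is corrected
#' per effect with the Greenhouse-Geisser epsilon (Huynh-Feldt available via
#' \code{correction}), estimated from the covariance matrix of the
#' orthonormalized effect contrasts over subjects; p-values use the
#' corrected degrees of freedom. Partial eta-squared is the
#' sums-of-squares ratio SS_effect / (SS_effect + SS_error) with a 95
#' percent confidence interval from inverting the noncentral-F distribution.
#'
#' @param data long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param within character vector (length 1 or 2) of within-subject factor
#'   columns.
#' @param subject name of the subject identifier column.
#' @param correction "gg" (Greenhouse-Geisser, default), "hf" (Huynh-Feldt)
#'   or "none".
#' @return an \linkS4class{AnovaResult}.
#' @examples
#' d <- generateRatings(genParams(nSubjects = 12), seed = 3)
#' rmAnova(d, "rating", c("orientation_deg", "context"), "subject")
#' @export
rmAnova <- function(data, dv, within, subject,
                    correction = c("gg", "hf", "none")) {
  correction <- match.arg(correction)
  stopifnot(length(within) %in% c(1L, 2L))
  agg <- stats::aggregate(data[[dv]],
                          c(data[subject], data[within]), mean)
  names(agg)[ncol(agg)] <- ".y"
  for (w in within) agg[[w]] <- factor(agg[[w]])
  agg[[subject]] <- factor(agg[[subject]])
  s <- nlevels(agg[[subject]])
  if (s < 3L) stop("need >= 3 subjects")
  lv <- lapply(within, function(w) levels(agg[[w]]))
  nlv <- vapply(lv, length, 1L)
  if (nrow(agg) != s * prod(nlv))
    stop("incomplete design: every subject must contribute every cell")

  # subject x cell matrix, cells ordered with factor 1 varying slowest
  ord <- do.call(order, c(agg[within], agg[subject]))
  agg <- agg[ord, ]
  Y <- matrix(agg$.y, nrow = s)   # s x (prod cells), subject varies fastest

  effectsList <- if (length(within) == 1L) {
    list(list(name = within[1], which = 1L))
  } else {
    list(list(name = within[1], which = 1L),
         list(name = within[2], which = 2L),
         list(name = paste(within, collapse = " x "), which = c(1L, 2L)))
  }

  rows <- lapply(effectsList, function(ef) {
    rmEffectRow(Y, nlv, ef$which, ef$name, s, correction)
  })
  new("AnovaResult", effects = do.call(rbind, rows))
}

# orthonormal contrast matrix spanning deviations from the mean
orthoContrasts <- function(k) {
  cm <- stats::contr.helmert(k)
  sweep(cm, 2, sqrt(colSums(cm^2)), "/")
}

# one effect row: project cells onto the effect's contrast space
rmEffectRow <- function(Y, nlv, which, name, s, correction) {
  # cell order: factor 1 slowest, factor 2 fastest (within factor 1)
  Cs <- lapply(seq_along(nlv), function(i) {
    if (i %in% which) orthoContrasts(nlv[i])
    else matrix(1 / sqrt(nlv[i]), nlv[i], 1)
  })
  C <- if (length(nlv) == 1L) Cs[[1]] else kronecker(Cs[[1]], Cs[[2]])
  scores <- Y %*% C                       # s x d effect scores
  d1 <- ncol(scores)
  m <- colMeans(scores)
  ssEffect <- s * sum(m^2)
  resid <- sweep(scores, 2, m)
  ssError <- sum(resid^2)
  d2 <- d1 * (s - 1)
  msE <- ssEffect / d1
  msR <- ssError / d2
  Fv <- msE / msR
  Sigma <- stats::cov(scores)
  tr <- sum(diag(Sigma))
  eps <- if (d1 == 1L) 1 else tr^2 / (d1 * sum(Sigma^2))
  if (correction == "hf" && d1 > 1L) {
    eps <- min(1, (s * d1 * eps - 2) / (d1 * (s - 1 - d1 * eps)))
  } else if (correction == "none") eps <- 1
  eps <- max(eps, 1 / d1)
  p <- stats::pf(Fv, d1 * eps, d2 * eps, lower.tail = FALSE)
  pes <- ssEffect / (ssEffect + ssError)
  ci <- partialEtaSqCI(Fv, d1 * eps, d2 * eps)
  data.frame(effect = name, F = Fv, df1_unc = d1, df2_unc = d2,
             epsilon = eps, df1_corr = d1 * eps, df2_corr = d2 * eps,
             p = p, pes = pes, pes_lo = ci[1], pes_hi = ci[2],
             ss_effect = ssEffect, ss_error = ssError)
}
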