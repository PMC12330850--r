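#' Paired t-test with Cohen's d and a noncentral-t confidence interval
#'
#' The t statistic is computed on the paired differences; Cohen's d uses
#' the difference-score standardization d = t / sqrt(n), which reproduces
#' the printed (t, d) pairs of the reporting convention this package
#' follows. The 95 percent CI for d inverts the noncentral-t distribution
#' at the 2.5/97.5 percentiles of the noncentrality parameter and divides
#' by sqrt(n).
#'
#' @param x,y per-subject paired values (equal length n >= 2).
#' @param conf confidence level, default 0.95.
#' @return a \linkS4class{TTestResult}.
#' @examples
#' set.seed(1)
#' x <- rnorm(20); y <- x + rnorm(20, 0.5, 0.5)
#' pairedT(y, x)
#' @export
pairedT <- function(x, y, conf = 0.95) {
  n <- length(x)
  if (length(y) != n || n < 2L) stop("x and y must have equal length >= 2")
  diffs <- x - y
  if (stats::sd(diffs) < .Machine$double.eps)
    stop("zero variance of the paired differences")
  tt <- stats::t.test(x, y, paired = TRUE)
  tv <- unname(tt$statistic)
  ci <- cohensDCI(tv, df = n - 1L, n = n, conf = conf)
  new("TTestResult", t = tv, df = as.numeric(n - 1L), p = tt$p.value,
      d = cohensD(tv, n), dLo = ci[1], dHi = ci[2], n = as.integer(n))
}

#' Cohen's d for paired designs from the t statistic
#'
#' @param t paired t statistic.
#' @param n number of pairs.
#' @return d = t / sqrt(n).
#' @export
cohensD <- function(t, n) t / sqrt(n)

#' Noncentral-t confidence interval for paired Cohen's d
#'
#' Finds the noncentrality parameters at which the observed t sits at the
#' upper and lower (1 - conf)/2 tails and maps them to the d scale.
#'
#' @param t observed paired t statistic.
#' @param df degrees of freedom (n - 1).
#' @param n number of pairs.
#' @param conf confidence level, default 0.95.
#' @return numeric(2), lower and upper bound on d.
#' @export
cohensDCI <- function(t, df, n, conf = 0.95) {
  alpha <- (1 - conf) / 2
  lo <- ncpFromT(t, df, prob = 1 - alpha)
  hi <- ncpFromT(t, df, prob = alpha)
  c(lo, hi) / sqrt(n)
}

# solve pt(t, df, ncp) = prob for ncp (pt is decreasing in ncp)
ncpFromT <- function(t, df, prob) {
  f <- function(ncp) suppressWarnings(stats::pt(t, df, ncp)) - prob
  span <- max(10, abs(t))
  stats::uniroot(f, interval = c(t - span, t + span), extendInt = "yes",
                 tol = 1e-9)$root
}

#' Partial eta-squared with a noncentral-F confidence interval
#'
#' pes = F df1 / (F df1 + df2). The CI inverts the noncentral-F
#' distribution for the noncentrality parameter lambda and maps it through
#' lambda / (lambda + df1 + df2 + 1).
#'
#' @param F observed F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @param conf confidence level, default 0.95.
#' @return for \code{partialEtaSq} the point estimate; for
#'   \code{partialEtaSqCI} numeric(2) with the interval (lower bounded at 0).
#' @examples
#' partialEtaSq(10.96, 1, 47)   # 0.19
#' @export
partialEtaSq <- function(F, df1, df2) F * df1 / (F * df1 + df2)

#' @rdname partialEtaSq
#' @export
partialEtaSqCI <- function(F, df1, df2, conf = 0.95) {
  alpha <- (1 - conf) / 2
  lamLo <- ncpFromF(F, df1, df2, prob = 1 - alpha)
  lamHi <- ncpFromF(F, df1, df2, prob = alpha)
  lam <- pmax(0, c(lamLo, lamHi))
  lam / (lam + df1 + df2 + 1)
}

# solve pf(F, df1, df2, ncp) = prob for ncp >= 0 (pf decreasing in ncp)
ncpFromF <- function(F, df1, df2, prob) {
  f <- function(ncp) stats::pf(F, df1, df2, ncp = ncp) - prob
  if (f(0) < 0) return(0)      # observed F already below the prob quantile
  upper <- max(10, 4 * (F * df1 + df1))
  while (f(upper) > 0 && upper < 1e7) upper <- upper * 4
  stats::uniroot(f, interval = c(0, upper), tol = 1e-9)$root
}
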