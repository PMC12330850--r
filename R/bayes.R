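#' Pre-specified cue-pattern weight models
#'
#' "sharpening" is the lateral-inhibition pattern expressed as a difference
#' of two Gaussians (+0.5, -1, -2, +5, -2, -1, +0.5); "generalization" a
#' quadratic similarity trend (-3, +0.5, +1.5, +2, +1.5, +0.5, -3), both
#' over the orientations +15, +25, +35, +45 (CS+), +55, +65, +75 deg. The
#' -45 deg cue is outside the published vectors and is excluded from the
#' Bayesian models.
#'
#' @param name "sharpening" or "generalization".
#' @return a \linkS4class{WeightModel}.
#' @examples
#' weightModel("generalization")
#' @export
weightModel <- function(name = c("sharpening", "generalization")) {
  name <- match.arg(name)
  w <- switch(name,
              sharpening = c(0.5, -1, -2, 5, -2, -1, 0.5),
              generalization = c(-3, 0.5, 1.5, 2, 1.5, 0.5, -3))
  new("WeightModel", name = name, levels = WEIGHTED_ORIENTATIONS, weights = w)
}

#' Build a JZS design from condition-level responses
#'
#' Maps subject x orientation x context responses onto a linear-model
#' design: one fixed column of weight scores (if a cue-pattern model is
#' given), one fixed column coding context as centred +-0.5 (aversive
#' positive), and subject random intercepts. Responses must be restricted
#' to the seven weighted orientations. All fixed columns are centred.
#'
#' @param responses data.frame with columns subject, orientation_deg,
#'   context (ignored when \code{includeContext = FALSE}) and the response
#'   column named in \code{dv}.
#' @param model a \linkS4class{WeightModel} or NULL for a context-only
#'   design.
#' @param includeContext include the context indicator, default TRUE.
#' @param dv response column name, default "response".
#' @return a list of class "jzsDesign": y, fixed (n x p centred matrix,
#'   possibly zero columns), subject (factor).
#' @export
buildDesign <- function(responses, model = NULL, includeContext = TRUE,
                        dv = "response") {
  if (!is.null(model)) {
    bad <- setdiff(unique(responses$orientation_deg), model@levels)
    if (length(bad))
      stop("orientation(s) outside the weight-model levels: ",
           paste(bad, collapse = ", "))
  }
  y <- responses[[dv]]
  cols <- list()
  if (!is.null(model))
    cols$weights <- model@weights[match(responses$orientation_deg,
                                        model@levels)]
  if (includeContext) {
    ctx <- responses$context
    if (!all(ctx %in% c("aversive", "neutral")))
      stop("context must be aversive/neutral for the context predictor")
    cols$context <- ifelse(ctx == "aversive", 0.5, -0.5)
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = length(y), ncol = 0)
  if (ncol(X)) X <- sweep(X, 2, colMeans(X))
  structure(list(y = y, fixed = X,
                 subject = factor(responses$subject)),
            class = "jzsDesign")
}

#' JZS Bayes factor of a mixed design against the random-intercept null
#'
#' Computes the Zellner-Siow default Bayes factor of the model {fixed
#' effects of interest + subject random intercepts} against the null
#' {subject random intercepts only}: standardized fixed slopes share a
#' g-prior with Cauchy scale \code{rscaleFixed} (0.5), the random-intercept
#' standard deviation a Cauchy scale \code{rscaleRandom} (1), and the error
#' variance a Jeffreys prior. Conditional on the two g parameters the
#' marginal-likelihood ratio is available in closed form; the g's are
#' integrated out by adaptive quadrature after a probit change of variables
#' that maps the half-Cauchy mixing densities onto the unit square.
#' Without random intercepts a single quadrature remains; with no fixed
#' effects of interest the comparison is null-vs-null and log BF = 0.
#'
#' @param design a "jzsDesign" from \code{buildDesign} (or a compatible
#'   list).
#' @param rscaleFixed Cauchy scale of the fixed-effect prior, default 0.5.
#' @param rscaleRandom Cauchy scale of the random-intercept prior,
#'   default 1.
#' @param relTol quadrature relative tolerance, default 1e-6.
#' @return the natural-log Bayes factor (model vs null).
#' @export
jzsBf <- function(design, rscaleFixed = 0.5, rscaleRandom = 1,
                  relTol = 1e-6) {
  y <- design$y
  if (any(!is.finite(y))) stop("responses must be finite")
  Xf <- design$fixed
  pF <- ncol(Xf)
  if (pF == 0L) return(0)
  # standardize fixed columns: the Cauchy prior is on standardized slopes
  sds <- apply(Xf, 2, stats::sd)
  if (any(sds < 1e-12)) stop("constant fixed-effect column")
  Xf <- sweep(sweep(Xf, 2, colMeans(Xf)), 2, sds, "/")
  hasZ <- !is.null(design$subject) && nlevels(factor(design$subject)) > 1L
  n <- length(y)
  if (n <= pF) stop("need more rows than fixed effects")
  if (!hasZ) {
    return(jzsMarginal(y, Xf, rep(1L, pF), rscaleFixed, relTol))
  }
  subj <- factor(design$subject)
  Z <- stats::model.matrix(~ 0 + subj)
  logM1 <- jzsMarginal(y, cbind(Xf, Z),
                       c(rep(1L, pF), rep(2L, ncol(Z))),
                       c(rscaleFixed, rscaleRandom), relTol)
  logM0 <- jzsMarginal(y, Z, rep(1L, ncol(Z)), rscaleRandom, relTol)
  logM1 - logM0
}

# log of the marginal likelihood ratio of {X with g-priors per group} vs
# the fixed-effect-free model (intercept + Jeffreys error only), the g's
# integrated over their half-Cauchy mixing densities by quadrature
jzsMarginal <- function(y, X, groupIdx, rscales, relTol) {
  n <- length(y)
  pAll <- ncol(X)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  Xt1 <- crossprod(X, rep(1, n))
  yty <- sum(y^2)
  oty <- sum(y)
  Q0 <- yty - oty^2 / n
  nGroups <- max(groupIdx)

  logBFg <- function(g) {                 # conditional log BF given g
    gv <- g[groupIdx]
    W <- XtX + diag(1 / gv, pAll)
    ch <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Wi_Xty <- backsolve(ch, forwardsolve(t(ch), Xty))
    Wi_Xt1 <- backsolve(ch, forwardsolve(t(ch), Xt1))
    q_yy <- yty - sum(Xty * Wi_Xty)
    q_11 <- n - sum(Xt1 * Wi_Xt1)
    q_1y <- oty - sum(Xt1 * Wi_Xty)
    Qg <- q_yy - q_1y^2 / q_11
    if (Qg <= 0 || q_11 <= 0) return(-Inf)
    logDet <- 2 * sum(log(diag(ch))) + sum(log(gv))
    0.5 * (log(n) - log(q_11)) - 0.5 * logDet +
      (n - 1) / 2 * (log(Q0) - log(Qg))
  }

  # probit map: u in (0,1) -> half-normal z -> g = r^2 / z^2 carries the
  # half-Cauchy (inverse-gamma(1/2, r^2/2)) mixing density exactly
  gOfU <- function(u, r) { z <- stats::qnorm((1 + u) / 2); r^2 / z^2 }

  if (nGroups == 1L) {
    shift <- max(vapply(seq(0.02, 0.98, length.out = 25), function(u)
      logBFg(gOfU(u, rscales[1])), 0))
    val <- stats::integrate(function(u) {
      vapply(u, function(ui)
        exp(logBFg(gOfU(ui, rscales[1])) - shift), 0)
    }, 0, 1, rel.tol = relTol, stop.on.error = FALSE)
    checkQuad(val)
    return(shift + log(val$value))
  }
  us <- seq(0.02, 0.98, length.out = 13)
  grid <- outer(us, us, Vectorize(function(u1, u2)
    logBFg(c(gOfU(u1, rscales[1]), gOfU(u2, rscales[2])))))
  shift <- max(grid)
  inner <- function(u1) {
    val <- stats::integrate(function(u2) {
      vapply(u2, function(u2i)
        exp(logBFg(c(gOfU(u1, rscales[1]), gOfU(u2i, rscales[2]))) -
              shift), 0)
    }, 0, 1, rel.tol = relTol * 0.1, stop.on.error = FALSE)
    checkQuad(val)
    val$value
  }
  val <- stats::integrate(function(u1) vapply(u1, inner, 0), 0, 1,
                          rel.tol = relTol, stop.on.error = FALSE)
  checkQuad(val)
  shift + log(val$value)
}

checkQuad <- function(val) {
  if (!is.finite(val$value) || val$value <= 0)
    stop("JZS quadrature failed to converge (value = ", val$value,
         ", abs.error = ", val$abs.error, ")")
  invisible(val)
}

#' Log Bayes-factor topographies for the candidate weight models
#'
#' Runs the JZS comparison independently per sensor, frequency and model.
#' The context model compares {context + subject intercepts} against the
#' random-intercept null directly. The cue-pattern models (sharpening,
#' generalization) are transitive comparisons: log BF(weights + context vs
#' null) - log BF(context vs null), i.e. the cue pattern is evaluated over
#' and above the context effect through the common null, which isolates the
#' cue main effect. Per-sensor failures are recorded as NA.
#'
#' @param snrBySensor data.frame with columns subject, orientation_deg,
#'   context, frequency_hz, sensor, snr (the -45 deg cue is dropped
#'   internally).
#' @param models list of WeightModel objects, default both published
#'   patterns.
#' @param frequencies frequencies (Hz) to map, default c(7.5, 15).
#' @param ... passed to \code{jzsBf}.
#' @return a \linkS4class{BFMap}.
#' @export
bfTopography <- function(snrBySensor,
                         models = list(weightModel("sharpening"),
                                       weightModel("generalization")),
                         frequencies = c(7.5, 15), ...) {
  dat <- snrBySensor[snrBySensor$orientation_deg %in% WEIGHTED_ORIENTATIONS, ]
  sensors <- unique(dat$sensor)
  out <- list()
  for (f in frequencies) {
    df <- dat[dat$frequency_hz == f, ]
    for (se in sensors) {
      ds <- df[df$sensor == se, ]
      ds$response <- ds$snr
      ctxBf <- tryCatch(
        jzsBf(buildDesign(ds, model = NULL, includeContext = TRUE), ...),
        error = function(e) NA_real_)
      rows <- data.frame(sensor = se, frequency_hz = f, model = "context",
                         log_bf = ctxBf)
      for (mo in models) {
        full <- tryCatch(
          jzsBf(buildDesign(ds, model = mo, includeContext = TRUE), ...),
          error = function(e) NA_real_)
        rows <- rbind(rows, data.frame(sensor = se, frequency_hz = f,
                                       model = mo@name,
                                       log_bf = full - ctxBf))
      }
      out[[length(out) + 1L]] <- rows
    }
  }
  new("BFMap", map = do.call(rbind, out))
}
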