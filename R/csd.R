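#' Current-source-density (surface Laplacian) transform
#'
#' Spherical-spline surface Laplacian of condition-average waveforms: the
#' interpolation matrix G and Laplacian matrix H are built from Legendre
#' series of the inter-sensor cosines (spline order m, \code{nTerms}
#' polynomial terms), G is regularized by adding \code{lambda} to its
#' diagonal, the spline coefficients are solved per time sample under the
#' zero-sum constraint, and the output is the H-projection of the
#' coefficients. The transform is linear in the input and maps a spatially
#' constant topography to (numerically) zero. lambda = 0.2 follows the
#' dense-array recommendation.
#'
#' @param avg a \linkS4class{ConditionAverage} (>= 32 sensors).
#' @param net a SensorNet with matching sensors.
#' @param lambda regularization added to the diagonal of G, default 0.2.
#' @param m spline order, default 4.
#' @param nTerms Legendre series length, default 50.
#' @return a ConditionAverage with units "CSD".
#' @export
csdTransform <- function(avg, net, lambda = 0.2, m = 4, nTerms = 50) {
  stopifnot(identical(sensorIds(net), avg@sensorIds))
  if (lambda < 0) stop("lambda must be >= 0")
  nSens <- length(avg@sensorIds)
  if (nSens < 32) stop("CSD needs >= 32 sensors with valid positions")
  TT <- csdMatrix(net@positions, lambda, m, nTerms)
  d <- dim(avg@data)
  out <- avg@data
  for (cc in seq_len(d[1]))
    out[cc, , ] <- TT %*% avg@data[cc, , ]
  initialize(avg, data = out, units = "CSD")
}

#' Dense CSD transform matrix from sensor positions
#'
#' Returns the (sensors x sensors) linear operator mapping a scalp
#' topography to its spherical-spline surface Laplacian. Exposed so the
#' operator can be inspected and cross-checked directly.
#'
#' @param positions unit-sphere sensor coordinates (sensors x 3).
#' @param lambda,m,nTerms as in \code{csdTransform}.
#' @return numeric matrix.
#' @export
csdMatrix <- function(positions, lambda = 0.2, m = 4, nTerms = 50) {
  cosg <- tcrossprod(positions)
  cosg[cosg > 1] <- 1; cosg[cosg < -1] <- -1
  if (any(duplicated(round(positions, 9))))
    stop("duplicate sensor positions make the spline system singular")
  n <- seq_len(nTerms)
  gCoef <- (2 * n + 1) / (n^m * (n + 1)^m)
  hCoef <- gCoef * n * (n + 1)              # -Laplace-Beltrami eigenvalues
  P <- legendreP(as.vector(cosg), nTerms)
  nSens <- nrow(positions)
  G <- matrix(P %*% gCoef / (4 * pi), nSens, nSens)
  H <- matrix(P %*% hCoef / (4 * pi), nSens, nSens)
  # bordered system [G + lambda I, 1; 1', 0]; solve for coefficients, then
  # project through H: csd = H %*% C where [C; c0'] = Ainv[, 1:n] acting on v
  A <- rbind(cbind(G + diag(lambda, nSens), 1), c(rep(1, nSens), 0))
  Ainv <- solve(A)
  Cmat <- Ainv[seq_len(nSens), seq_len(nSens)]
  H %*% Cmat
}
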