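#' Construct a synthetic dense-array sensor net
#'
#' Builds an EGI-like geodesic layout on the unit sphere: sensors are placed
#' by a Fibonacci lattice over a spherical cap covering the head surface,
#' the sensor closest to the vertex is labelled "Cz", and the eight sensors
#' closest to the occipital pole are given the canonical pool labels (EGI
#' sensors 70, 71, 72, 74, 75, 76, 82, 83; "E75" plays the role of Oz).
#' The geometry is synthetic -- it emulates the coverage and local spacing
#' of a 129-channel geodesic net without reproducing the vendor's exact
#' coordinates, which the analysis does not require: only the pool identity
#' and a plausible spherical geometry enter the pipeline.
#'
#' @param nSensors number of sensors (>= 16); 129 is the reference layout.
#' @param zMin lower cap boundary (default -0.4, i.e. coverage extending
#'   below the equator as with geodesic nets).
#' @return a \linkS4class{SensorNet}.
#' @examples
#' net <- egiSensorNet(129)
#' occipitalPool(net)
#' @export
egiSensorNet <- function(nSensors = 129L, zMin = -0.4) {
  nSensors <- as.integer(nSensors)
  stopifnot(nSensors >= 16L)
  i <- seq_len(nSensors)
  # Fibonacci lattice over the cap z in [zMin, 1]
  z <- 1 - (i - 0.5) / nSensors * (1 - zMin)
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  pos <- pos / sqrt(rowSums(pos^2))

  ozDir <- c(0, -1, 0)                     # occipital pole
  czDir <- c(0, 0, 1)                      # vertex
  dOz <- order(-(pos %*% ozDir))
  poolIdx <- dOz[1:8]
  czIdx <- which.max(pos %*% czDir)
  if (czIdx %in% poolIdx) czIdx <- setdiff(order(-(pos %*% czDir)), poolIdx)[1]

  ids <- character(nSensors)
  poolLabels <- c("E75", "E70", "E71", "E72", "E74", "E76", "E82", "E83")
  ids[poolIdx] <- poolLabels                 # nearest to the pole becomes E75/Oz
  ids[czIdx] <- "Cz"
  free <- setdiff(paste0("E", seq_len(2 * nSensors)),
                  c(poolLabels, "Cz"))
  ids[ids == ""] <- free[seq_len(sum(ids == ""))]

  new("SensorNet", sensorIds = ids, positions = pos,
      occipitalPool = poolLabels)
}

#' Write / read a whitespace-delimited electrode position file
#'
#' Format: one line per sensor, \code{name x y z}, unit-sphere coordinates.
#'
#' @param net a SensorNet.
#' @param path file path.
#' @param pool pool labels to use when reading (default: the 8 sensors
#'   nearest the occipital pole direction).
#' @return \code{readSensorNet} returns a SensorNet.
#' @export
writeSensorNet <- function(net, path) {
  df <- data.frame(name = net@sensorIds, net@positions)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeSensorNet
#' @export
readSensorNet <- function(path, pool = NULL) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("name", "x", "y", "z"))
  pos <- as.matrix(df[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  if (is.null(pool)) {
    ozDir <- c(0, -1, 0)
    pool <- df$name[order(-(pos %*% ozDir))][1:8]
  }
  new("SensorNet", sensorIds = as.character(df$name), positions = pos,
      occipitalPool = as.character(pool))
}
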