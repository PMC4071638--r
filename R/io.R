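## Readers and writers: delimited text with JSON sidecars, edge-list
## TSV, GraphML.  All writers round-trip: write followed by read
## reproduces the object.

jsonSidecarPath <- function(path) paste0(path, ".json")

writeSidecar <- function(path, meta) {
  jsonlite::write_json(meta, jsonSidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
}

#' Read and write multichannel time series
#'
#' Time series are stored as a locations x samples TSV (no header) with
#' a JSON sidecar `<path>.json` carrying the sampling rate and location
#' identifiers.
#'
#' @param x a [TimeSeriesSet-class].
#' @param path file path (TSV).
#' @return `writeTimeSeries()` the path invisibly; `readTimeSeries()` a
#'   [TimeSeriesSet-class].
#' @export
writeTimeSeries <- function(x, path) {
  stopifnot(is(x, "TimeSeriesSet"))
  write.table(x@data, path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  writeSidecar(path, list(fs = x@fs, locationIds = as.list(x@locationIds)))
  invisible(path)
}

#' @rdname writeTimeSeries
#' @export
readTimeSeries <- function(path) {
  side <- jsonSidecarPath(path)
  if (!file.exists(side))
    stop(sprintf("missing JSON sidecar '%s'", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  data <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(data) <- NULL
  makeTimeSeriesSet(data, meta$fs, meta$locationIds)
}

#' Read and write PLV matrices
#'
#' Dense symmetric matrix TSV plus a JSON sidecar with the frequency /
#' band descriptor, sample count and location identifiers.
#'
#' @param x a [PLVMatrix-class].
#' @param path file path (TSV).
#' @return `writePLVMatrix()` the path invisibly; `readPLVMatrix()` a
#'   [PLVMatrix-class].
#' @export
writePLVMatrix <- function(x, path) {
  stopifnot(is(x, "PLVMatrix"))
  write.table(format(x@values, digits = 17, trim = TRUE, scientific = TRUE),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  writeSidecar(path, list(f0 = x@f0, band = x@band,
                          nSamples = x@nSamples,
                          locationIds = as.list(x@locationIds)))
  invisible(path)
}

#' @rdname writePLVMatrix
#' @export
readPLVMatrix <- function(path) {
  side <- jsonSidecarPath(path)
  if (!file.exists(side))
    stop(sprintf("missing JSON sidecar '%s'", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  V <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(V) <- NULL
  V <- (V + t(V)) / 2
  diag(V) <- 0
  new("PLVMatrix", values = V,
      f0 = if (is.null(meta$f0)) NA_real_ else as.numeric(meta$f0),
      band = meta$band, nSamples = as.integer(meta$nSamples),
      locationIds = as.character(meta$locationIds))
}

#' Write a centrality vector as TSV
#'
#' Two-column TSV of (locationId, score).
#'
#' @param x a [CentralityVector-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCentrality <- function(x, path) {
  stopifnot(is(x, "CentralityVector"))
  write.table(data.frame(locationId = x@locationIds, score = x@scores),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write parcellations
#'
#' Per-vertex label TSV plus a JSON sidecar with k, seed, objective and
#' centroid indices.
#'
#' @param x a [Parcellation-class].
#' @param path file path (TSV).
#' @return `writeParcellation()` the path invisibly;
#'   `readParcellation()` a [Parcellation-class].
#' @export
writeParcellation <- function(x, path) {
  stopifnot(is(x, "Parcellation"))
  write.table(data.frame(vertex = seq_along(x@labels), label = x@labels),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  writeSidecar(path, list(k = x@k, seed = x@seed,
                          objective = x@objective,
                          centroids = as.list(x@centroids),
                          iterations = x@iterations,
                          converged = x@converged))
  invisible(path)
}

#' @rdname writeParcellation
#' @export
readParcellation <- function(path) {
  meta <- jsonlite::read_json(jsonSidecarPath(path),
                              simplifyVector = TRUE)
  tab <- read.table(path, sep = "\t", header = TRUE)
  new("Parcellation", labels = as.integer(tab$label),
      centroids = as.integer(meta$centroids),
      objective = as.numeric(meta$objective), k = as.integer(meta$k),
      seed = as.integer(meta$seed),
      iterations = as.integer(meta$iterations),
      converged = as.logical(meta$converged))
}

#' Write a region network
#'
#' Edge-list TSV sorted by (regionA, regionB); optionally also GraphML
#' (via igraph) for network tools.
#'
#' @param x a [RegionNetwork-class].
#' @param path output TSV path.
#' @param graphml optional GraphML output path.
#' @return the TSV path, invisibly.
#' @export
writeRegionNetwork <- function(x, path, graphml = NULL) {
  stopifnot(is(x, "RegionNetwork"))
  edges <- x@edges[order(x@edges$regionA, x@edges$regionB), ]
  write.table(edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  writeSidecar(path, list(k = x@k, alpha = x@alpha))
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      edges[edges$significant, c("regionA", "regionB", "observed", "p")],
      directed = FALSE,
      vertices = data.frame(name = seq_len(x@k)))
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

#' @rdname writeRegionNetwork
#' @export
readRegionNetwork <- function(path) {
  meta <- jsonlite::read_json(jsonSidecarPath(path),
                              simplifyVector = TRUE)
  edges <- read.table(path, sep = "\t", header = TRUE)
  new("RegionNetwork", k = as.integer(meta$k), edges = edges,
      alpha = as.numeric(meta$alpha))
}

#' Band-pass filter and downsample a time-series set
#'
#' Optional preprocessing mirroring typical recording pipelines: an
#' FFT brick-wall band-pass (default 1--50 Hz) and integer-factor
#' decimation.  Synthetic data are generated at the analysis rate
#' directly and do not need this step.
#'
#' @param x a [TimeSeriesSet-class].
#' @param low,high band edges in Hz.
#' @param downTo target sampling rate (must divide fs; NULL = keep).
#' @return a filtered [TimeSeriesSet-class].
#' @export
bandpassResample <- function(x, low = 1, high = 50, downTo = NULL) {
  stopifnot(is(x, "TimeSeriesSet"))
  N <- ncol(x@data)
  fr <- (seq_len(N) - 1L) / N * x@fs
  fr <- pmin(fr, x@fs - fr)            # two-sided frequency axis
  keep <- fr >= low & fr <= high
  X <- mvfft(t(x@data))
  X[!keep, ] <- 0
  y <- Re(mvfft(X, inverse = TRUE)) / N
  out <- t(y)
  fs <- x@fs
  if (!is.null(downTo)) {
    fac <- fs / downTo
    if (fac %% 1 != 0) stop("downTo must divide the sampling rate")
    out <- out[, seq(1L, N, by = as.integer(fac)), drop = FALSE]
    fs <- downTo
  }
  makeTimeSeriesSet(out, fs, x@locationIds)
}
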