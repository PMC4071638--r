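## S4 classes for the pipeline's central objects.

#' Morlet wavelet specification
#'
#' Describes the complex Morlet analysis wavelet at one center frequency
#' under the constant spectral-ratio convention `f0 / sigmaF = cRatio`,
#' with the reciprocal bandwidth relation `sigmaF = 1 / (2 * pi * sigmaT)`.
#'
#' @slot f0 center frequency (Hz).
#' @slot cRatio constant spectral ratio (dimensionless).
#' @slot sigmaF spectral bandwidth (Hz).
#' @slot sigmaT temporal bandwidth (s).
#' @seealso [makeWaveletSpec()]
#' @export
setClass("WaveletSpec",
  representation(f0 = "numeric", cRatio = "numeric",
                 sigmaF = "numeric", sigmaT = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@f0) != 1L || !is.finite(object@f0) || object@f0 <= 0)
      msg <- c(msg, "f0 must be a single positive number")
    if (length(object@cRatio) != 1L || !is.finite(object@cRatio) ||
        object@cRatio <= 0)
      msg <- c(msg, "cRatio must be a single positive number")
    if (length(msg)) return(msg)
    if (abs(object@sigmaF - object@f0 / object@cRatio) >
        1e-12 * object@sigmaF)
      msg <- c(msg, "sigmaF must equal f0 / cRatio")
    if (abs(object@sigmaT - 1 / (2 * pi * object@sigmaF)) >
        1e-12 * object@sigmaT)
      msg <- c(msg, "sigmaT must equal 1 / (2 * pi * sigmaF)")
    if (length(msg)) msg else TRUE
  })

#' Multichannel time series at known sampling rate
#'
#' A set of L location-wise signals sampled at `fs` Hz, stored as an
#' L x N matrix (rows are locations).
#'
#' @slot data numeric matrix, locations x samples.
#' @slot fs sampling rate (Hz).
#' @slot locationIds character vector of row identifiers.
#' @export
setClass("TimeSeriesSet",
  representation(data = "matrix", fs = "numeric", locationIds = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@data) || ncol(object@data) < 1L)
      msg <- c(msg, "data must be a numeric matrix with at least one sample")
    if (anyNA(object@data))
      msg <- c(msg, "data must not contain missing samples")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    if (length(object@locationIds) != nrow(object@data))
      msg <- c(msg, "locationIds must match the number of rows")
    if (length(msg)) msg else TRUE
  })

#' Instantaneous phase trajectories at one analysis frequency
#'
#' Phases (radians, in (-pi, pi]) of the complex Morlet coefficients for
#' every location, restricted to the samples retained after trimming the
#' wavelet half-support at both ends of the record.
#'
#' @slot phases numeric matrix, locations x retained samples.
#' @slot f0 analysis frequency (Hz).
#' @slot fs sampling rate of the parent series (Hz).
#' @slot validRange integer vector `c(first, last)`: the span of original
#'   sample indices retained after edge trimming.
#' @slot locationIds character row identifiers.
#' @export
setClass("PhaseSeries",
  representation(phases = "matrix", f0 = "numeric", fs = "numeric",
                 validRange = "integer", locationIds = "character"),
  validity = function(object) {
    msg <- character()
    if (any(object@phases > pi + 1e-9) || any(object@phases <= -pi - 1e-9))
      msg <- c(msg, "phases must lie in (-pi, pi]")
    if (length(object@validRange) != 2L ||
        diff(object@validRange) + 1L != ncol(object@phases))
      msg <- c(msg, "validRange must span exactly ncol(phases) samples")
    if (length(object@locationIds) != nrow(object@phases))
      msg <- c(msg, "locationIds must match the number of rows")
    if (length(msg)) msg else TRUE
  })

#' Symmetric matrix of time-averaged phase locking values
#'
#' The L x L adjacency of the phase-locking graph: entry (i, j) is the
#' time-averaged PLV between locations i and j, the diagonal is exactly
#' zero (no self-referential edges).
#'
#' @slot values numeric L x L matrix, symmetric, zero diagonal,
#'   off-diagonal entries in \[0, 1\].
#' @slot f0 analysis frequency in Hz (`NA` for band averages).
#' @slot band character description of the frequency content, e.g. "10"
#'   or "8:13".
#' @slot nSamples number of phase samples averaged per entry.
#' @slot locationIds character identifiers for rows/columns.
#' @export
setClass("PLVMatrix",
  representation(values = "matrix", f0 = "numeric", band = "character",
                 nSamples = "integer", locationIds = "character"),
  validity = function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
    if (any(abs(diag(v)) > 0)) msg <- c(msg, "diagonal must be exactly zero")
    if (any(v < -1e-12) || any(v > 1 + 1e-9))
      msg <- c(msg, "entries must lie in [0, 1]")
    if (max(abs(v - t(v))) > 1e-9) msg <- c(msg, "values must be symmetric")
    if (length(object@locationIds) != nrow(v))
      msg <- c(msg, "locationIds must match dimension")
    if (length(msg)) msg else TRUE
  })

#' Eigenvector centrality scores of the phase-locking graph
#'
#' The leading singular/eigen-vector of the PLV adjacency, oriented to be
#' entrywise non-negative and normalized to unit Euclidean norm.  Larger
#' scores mark dipoles that are better connected to other well-connected
#' dipoles.
#'
#' @slot scores numeric vector, non-negative, unit L2 norm.
#' @slot locationIds character identifiers.
#' @export
setClass("CentralityVector",
  representation(scores = "numeric", locationIds = "character"),
  validity = function(object) {
    msg <- character()
    if (any(object@scores < 0)) msg <- c(msg, "scores must be non-negative")
    if (abs(sum(object@scores^2) - 1) > 1e-8)
      msg <- c(msg, "scores must have unit Euclidean norm")
    if (length(object@locationIds) != length(object@scores))
      msg <- c(msg, "locationIds must match length of scores")
    if (length(msg)) msg else TRUE
  })

#' Triangulated surface geometry
#'
#' Vertex coordinates (cm) of a (spherically registered) surface plus a
#' triangle index list.  The face list may be empty when only vertex
#' positions are needed (e.g. clustering point clouds).
#'
#' @slot vertices numeric L x 3 matrix of coordinates.
#' @slot faces integer F x 3 matrix of 1-based vertex indices.
#' @export
setClass("SurfaceGeometry",
  representation(vertices = "matrix", faces = "matrix"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@vertices) != 3L)
      msg <- c(msg, "vertices must have three columns")
    if (!all(is.finite(object@vertices)))
      msg <- c(msg, "vertex coordinates must be finite")
    if (nrow(object@faces) > 0L) {
      if (ncol(object@faces) != 3L)
        msg <- c(msg, "faces must have three columns")
      else if (any(object@faces < 1L) ||
               any(object@faces > nrow(object@vertices)))
        msg <- c(msg, "face indices must lie in 1..nrow(vertices)")
    }
    if (length(msg)) msg else TRUE
  })

#' Parcellation of surface vertices into functionally defined regions
#'
#' Assignment of every vertex to one of k clusters produced by
#' cosine-distance k-means on standardized (x, y, z, centrality)
#' features.  Centroids are data points (snap-to-datapoint heuristic),
#' identified by vertex index.
#'
#' @slot labels integer vector in 1..k, one entry per vertex.
#' @slot centroids integer vector of k vertex indices; the centroid of
#'   cluster j carries label j.
#' @slot objective final summed within-cluster cosine distance.
#' @slot k number of clusters.
#' @slot seed RNG seed used.
#' @slot iterations iterations used by the winning restart.
#' @slot converged logical; FALSE if the iteration cap was hit.
#' @export
setClass("Parcellation",
  representation(labels = "integer", centroids = "integer",
                 objective = "numeric", k = "integer", seed = "integer",
                 iterations = "integer", converged = "logical"),
  validity = function(object) {
    msg <- character()
    k <- object@k
    if (length(object@centroids) != k)
      msg <- c(msg, "centroids must have length k")
    if (!all(sort(unique(object@labels)) == seq_len(k)))
      msg <- c(msg, "every label 1..k must be occupied")
    if (length(msg) == 0L &&
        !all(object@labels[object@centroids] == seq_len(k)))
      msg <- c(msg, "centroid of cluster j must carry label j")
    if (length(msg)) msg else TRUE
  })

#' Significance graph of region-pair permutation tests
#'
#' One row per unordered region pair with the observed
#' difference-of-means statistic, Monte-Carlo permutation p-value and
#' significance flag at level alpha.
#'
#' @slot k number of regions.
#' @slot edges data.frame with columns regionA, regionB, observed, p,
#'   nPerms, significant.
#' @slot alpha significance level used.
#' @export
setClass("RegionNetwork",
  representation(k = "integer", edges = "data.frame", alpha = "numeric"),
  validity = function(object) {
    k <- object@k
    msg <- character()
    if (nrow(object@edges) != k * (k - 1L) / 2L)
      msg <- c(msg, "edges must contain exactly k(k-1)/2 rows")
    need <- c("regionA", "regionB", "observed", "p", "nPerms", "significant")
    if (!all(need %in% names(object@edges)))
      msg <- c(msg, paste("edges must have columns:",
                          paste(need, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Minimum-norm inverse model
#'
#' The regularized linear inverse `W = R A' (A R A' + lambda2 C)^-1`
#' mapping sensor measurements to source amplitudes, with `lambda2 =
#' 1/SNR`.
#'
#' @slot A gain matrix, sensors x sources.
#' @slot sourceCov source covariance R, sources x sources.
#' @slot noiseCov sensor noise covariance C, sensors x sensors.
#' @slot snr assumed (power) signal-to-noise ratio.
#' @slot lambda2 regularization parameter, `1/snr`.
#' @slot W inverse operator, sources x sensors.
#' @export
setClass("InverseModel",
  representation(A = "matrix", sourceCov = "matrix",
                 noiseCov = "matrix", snr = "numeric",
                 lambda2 = "numeric", W = "matrix"))

#' Synthetic dataset description
#'
#' A fully seeded description of one synthetic study condition: the
#' generator kind, carrier frequencies, amplitudes, perturbations and
#' sampling metadata.  Identical scenarios (including seed) regenerate
#' bit-identical datasets.
#'
#' @slot kind one of "grid", "dipole_pair", "null".
#' @slot params named list of generator parameters.
#' @slot seed integer RNG seed.
#' @export
setClass("Scenario",
  representation(kind = "character", params = "list", seed = "integer"),
  validity = function(object) {
    if (!object@kind %in% c("grid", "dipole_pair", "null"))
      "kind must be one of grid, dipole_pair, null" else TRUE
  })
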