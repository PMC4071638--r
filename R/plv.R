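## Phase locking values: single pairs, all-by-all matrices, band averages.

#' Time-averaged phase locking value of two phase vectors
#'
#' \deqn{PLV = \frac{1}{N} \left| \sum_{n=1}^{N}
#'   e^{i(\theta_1(n) - \theta_2(n))} \right|}
#' PLV ranges from 0 (random phase relationship) to 1 (fixed phase
#' relationship) and is symmetric in its arguments.
#'
#' @param theta1,theta2 numeric phase vectors (radians) of equal length
#'   over a common valid range.
#' @return a value in \[0, 1\].
#' @examples
#' plv(runif(100, -pi, pi), runif(100, -pi, pi))  # near the noise floor
#' @export
plv <- function(theta1, theta2) {
  if (length(theta1) != length(theta2))
    stop("phase vectors must have equal length")
  if (length(theta1) < 1L) stop("empty valid range")
  min(Mod(mean(exp(1i * (theta1 - theta2)))), 1)
}

#' All-by-all phase locking matrix
#'
#' Extracts instantaneous phases for all L locations and computes the
#' L(L-1)/2 unique pairwise PLVs, returned as a symmetric matrix with a
#' zero diagonal.  Computation is chunked into row blocks using real
#' trigonometric cross-products; results are independent of the block
#' size.
#'
#' For records much longer than the wavelet's phase decorrelation time
#' the phase samples are heavily autocorrelated; `decimate = d` keeps
#' every d-th retained phase sample before averaging, reducing cost with
#' negligible effect on the estimate provided the decimated rate remains
#' well above twice the wavelet bandwidth.
#'
#' @param x a [TimeSeriesSet-class] with L >= 2 locations.
#' @param spec a [WaveletSpec-class].
#' @param blockSize rows per computation block.
#' @param decimate integer phase-sample decimation factor (default 1).
#' @return a [PLVMatrix-class].
#' @export
pairwisePLV <- function(x, spec, blockSize = 128L, decimate = 1L) {
  stopifnot(is(x, "TimeSeriesSet"))
  if (nrow(x@data) < 2L) stop("need at least two locations")
  ph <- instantaneousPhase(x, spec)
  phasePLV(ph, blockSize = blockSize, decimate = decimate)
}

#' @rdname pairwisePLV
#' @param phase a [PhaseSeries-class] (alternative entry point when the
#'   phases are already available).
#' @export
phasePLV <- function(phase, blockSize = 128L, decimate = 1L) {
  stopifnot(is(phase, "PhaseSeries"))
  P <- phase@phases
  if (decimate > 1L)
    P <- P[, seq(1L, ncol(P), by = as.integer(decimate)), drop = FALSE]
  L <- nrow(P)
  M <- ncol(P)
  Cs <- cos(P)
  Sn <- sin(P)
  V <- matrix(0, L, L)
  starts <- seq(1L, L, by = as.integer(blockSize))
  for (s in starts) {
    rb <- s:min(s + blockSize - 1L, L)
    re <- tcrossprod(Cs[rb, , drop = FALSE], Cs) +
          tcrossprod(Sn[rb, , drop = FALSE], Sn)
    im <- tcrossprod(Sn[rb, , drop = FALSE], Cs) -
          tcrossprod(Cs[rb, , drop = FALSE], Sn)
    V[rb, ] <- sqrt(re * re + im * im) / M
  }
  V <- (V + t(V)) / 2
  V[V > 1] <- 1
  diag(V) <- 0
  new("PLVMatrix", values = V, f0 = phase@f0,
      band = as.character(phase@f0), nSamples = M,
      locationIds = phase@locationIds)
}

#' Entrywise average of PLV matrices over a frequency band
#'
#' Averages matrices computed at integer frequencies within a band
#' (e.g. alpha, 8--13 Hz) into a single band-level adjacency.  All
#' inputs must share dimension and location ordering.
#'
#' @param matrices list of [PLVMatrix-class] objects.
#' @param band optional character label for the result (default joins
#'   the input labels).
#' @return a [PLVMatrix-class].
#' @export
bandAverage <- function(matrices, band = NULL) {
  if (!length(matrices)) stop("need at least one matrix")
  stopifnot(all(vapply(matrices, is, logical(1), "PLVMatrix")))
  ids <- matrices[[1L]]@locationIds
  dims <- nrow(matrices[[1L]]@values)
  for (m in matrices) {
    if (nrow(m@values) != dims) stop("matrix dimensions differ")
    if (!identical(m@locationIds, ids)) stop("location ordering differs")
  }
  V <- Reduce(`+`, lapply(matrices, slot, "values")) / length(matrices)
  diag(V) <- 0
  if (is.null(band))
    band <- paste(vapply(matrices, slot, character(1), "band"),
                  collapse = ",")
  new("PLVMatrix", values = V, f0 = NA_real_, band = band,
      nSamples = matrices[[1L]]@nSamples, locationIds = ids)
}

#' PLV matrices across a frequency grid
#'
#' Convenience wrapper computing [pairwisePLV()] at each of a set of
#' integer frequencies (default 5--40 Hz, the package's analysis grid).
#'
#' @inheritParams pairwisePLV
#' @param freqs numeric vector of analysis frequencies in Hz.
#' @param c constant spectral ratio.
#' @return named list of [PLVMatrix-class] objects.
#' @export
frequencyGridPLV <- function(x, freqs = 5:40, c = 7, blockSize = 128L,
                             decimate = 1L) {
  res <- lapply(freqs, function(f)
    pairwisePLV(x, makeWaveletSpec(f, c), blockSize = blockSize,
                decimate = decimate))
  names(res) <- as.character(freqs)
  res
}
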