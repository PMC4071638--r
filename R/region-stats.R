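## Non-parametric permutation testing of region-pair connections.

#' Cross-region edge populations
#'
#' Collects the PLV values of all dipole-pair edges with one endpoint in
#' each of two disjoint regions, pooled across subjects when several
#' matrices are supplied.  Within-region edges are never included.
#'
#' @param plv a [PLVMatrix-class] or list of them (one per subject, same
#'   location ordering).
#' @param parc a [Parcellation-class].
#' @param a,b distinct region labels in 1..k.
#' @param condition tag recorded with the population ("rest" or "null").
#' @return list with elements `values`, `regionA`, `regionB`,
#'   `condition`.
#' @export
collectEdgeValues <- function(plv, parc, a, b, condition = "rest") {
  if (is(plv, "PLVMatrix")) plv <- list(plv)
  stopifnot(is(parc, "Parcellation"))
  a <- as.integer(a); b <- as.integer(b)
  if (a == b) stop("self-comparison of a region is undefined")
  labels <- parcelLabels(parc)
  ia <- which(labels == a)
  ib <- which(labels == b)
  if (!length(ia) || !length(ib)) stop("regions must be non-empty")
  vals <- unlist(lapply(plv, function(m)
    as.vector(m@values[ia, ib, drop = FALSE])), use.names = FALSE)
  list(values = vals, regionA = a, regionB = b, condition = condition)
}

#' Monte-Carlo permutation test of two edge populations
#'
#' Tests whether the resting-state edge population exceeds the null
#' (signal-free) population using the difference of means as the test
#' statistic.  The pooled values are randomly re-partitioned; sampling
#' continues past `minPerms` permutations until the running p-estimate
#' changes by less than `stopTol` (relative) over a batch, or `maxPerms`
#' is reached.  The p-value estimator is `(b + 1) / (m + 1)` where b
#' counts permuted statistics at least as extreme as the observed one,
#' so p is never exactly zero.
#'
#' The default is one-sided (rest > null): signal-free recordings cannot
#' contain genuine coupling.  `alternative = "two.sided"` uses the
#' absolute statistic.
#'
#' @param rest,null edge populations from [collectEdgeValues()] (or
#'   plain numeric vectors).
#' @param alpha significance level in (0, 1].
#' @param minPerms minimum number of permutations (default 5000).
#' @param batch permutations added per convergence check (default 500).
#' @param stopTol relative change threshold of the running p-estimate
#'   (default 1e-4, i.e. 0.01%).
#' @param maxPerms hard cap on permutations (default 20000).
#' @param seed optional integer seed applied before sampling.
#' @param alternative "greater" (default) or "two.sided".
#' @return list of class `plvPermTest`: `observed`, `p`, `nPerms`,
#'   `significant`, `alpha`, `alternative`, `seed`.
#' @export
permutationTest <- function(rest, null, alpha = 0.05, minPerms = 5000L,
                            batch = 500L, stopTol = 1e-4,
                            maxPerms = 20000L, seed = NULL,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- if (is.list(rest)) rest$values else rest
  y <- if (is.list(null)) null$values else null
  if (!length(x) || !length(y)) stop("both populations must be non-empty")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  observed <- mean(x) - mean(y)
  r <- perm_mc(c(x, y), length(x), observed, as.integer(minPerms),
               as.integer(batch), stopTol, as.integer(maxPerms),
               alternative == "two.sided")
  p <- (r$b + 1) / (r$m + 1)
  structure(list(observed = observed, p = p, nPerms = r$m,
                 significant = p <= alpha, alpha = alpha,
                 alternative = alternative, seed = seed),
            class = "plvPermTest")
}

#' @export
print.plvPermTest <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s): observed = %.4g, p = %.4g (%d perms)%s\n",
    x$alternative, x$observed, x$p, x$nPerms,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Permutation-test network over all region pairs
#'
#' Runs [permutationTest()] for each of the k(k-1)/2 unordered region
#' pairs, comparing resting-state to null edge populations.  Per-pair
#' seeds are derived deterministically from the master seed, so the
#' network is reproducible and pairs are independent of evaluation
#' order.
#'
#' @param plvRest,plvNull a [PLVMatrix-class] or list of them (subjects)
#'   for the resting and null conditions.
#' @param parc a [Parcellation-class].
#' @param alpha significance level.
#' @param seed master integer seed.
#' @param maxEdges optional cap on each population's size; larger
#'   populations are randomly subsampled (seeded) to bound the cost of
#'   large-region pairs.
#' @inheritParams permutationTest
#' @return a [RegionNetwork-class].
#' @export
buildRegionNetwork <- function(plvRest, plvNull, parc, alpha = 0.05,
                               seed = 1L, minPerms = 5000L, batch = 500L,
                               stopTol = 1e-4, maxPerms = 20000L,
                               maxEdges = Inf,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is(parc, "Parcellation"))
  k <- parc@k
  pairs <- combn(k, 2L)
  nPairs <- ncol(pairs)
  set.seed(as.integer(seed))
  pairSeeds <- sample.int(.Machine$integer.max - 1L, nPairs)
  rows <- vector("list", nPairs)
  for (i in seq_len(nPairs)) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    rest <- collectEdgeValues(plvRest, parc, a, b, "rest")$values
    null <- collectEdgeValues(plvNull, parc, a, b, "null")$values
    set.seed(pairSeeds[i])
    if (is.finite(maxEdges)) {
      if (length(rest) > maxEdges)
        rest <- rest[sample.int(length(rest), maxEdges)]
      if (length(null) > maxEdges)
        null <- null[sample.int(length(null), maxEdges)]
    }
    tst <- permutationTest(rest, null, alpha = alpha, minPerms = minPerms,
                           batch = batch, stopTol = stopTol,
                           maxPerms = maxPerms, seed = NULL,
                           alternative = alternative)
    rows[[i]] <- data.frame(regionA = a, regionB = b,
                            observed = tst$observed, p = tst$p,
                            nPerms = tst$nPerms,
                            significant = tst$significant)
  }
  edges <- do.call(rbind, rows)
  edges <- edges[order(edges$regionA, edges$regionB), , drop = FALSE]
  rownames(edges) <- NULL
  new("RegionNetwork", k = k, edges = edges, alpha = alpha)
}

#' Null calibration of the full pipeline
#'
#' Empirically verifies the critical value: for each of `nPairs`
#' independent pairs of signal-free Gaussian-noise datasets, runs the
#' full pipeline (PLV, eigenvector centrality, k-means parcellation,
#' permutation network with one dataset as the null) and records the
#' fraction of region pairs declared significant.  Under the global null
#' this fraction estimates the false discovery rate and should bracket
#' alpha.
#'
#' @param nPairs number of dataset pairs (default 10).
#' @param alpha significance level.
#' @param nLocations number of source locations (on a unit sphere).
#' @param duration record length in seconds.
#' @param fs sampling rate in Hz.
#' @param f0 analysis frequency in Hz.
#' @param c constant spectral ratio of the wavelet.
#' @param k number of regions.
#' @param seed master seed.
#' @param nstart k-means restarts.
#' @inheritParams permutationTest
#' @param decimate phase decimation passed to [pairwisePLV()].
#' @return list with `mean`, `sd` and the per-pair `fractions`.
#' @export
nullCalibration <- function(nPairs = 10L, alpha = 0.05, nLocations = 200L,
                            duration = 60, fs = 250, f0 = 10, c = 7,
                            k = 40L, seed = 1L, minPerms = 5000L,
                            maxPerms = 20000L, stopTol = 1e-4,
                            nstart = 5L, decimate = 1L) {
  coords <- fibonacciSphere(nLocations)
  geom <- new("SurfaceGeometry", vertices = coords,
              faces = matrix(integer(), 0L, 3L))
  set.seed(as.integer(seed))
  pairSeeds <- matrix(sample.int(.Machine$integer.max - 1L, 3L * nPairs),
                      nrow = nPairs)
  spec <- makeWaveletSpec(f0, c)
  N <- round(duration * fs)
  fractions <- vapply(seq_len(nPairs), function(i) {
    set.seed(pairSeeds[i, 1L])
    rest <- makeTimeSeriesSet(
      matrix(rnorm(nLocations * N), nLocations, N), fs)
    set.seed(pairSeeds[i, 2L])
    null <- makeTimeSeriesSet(
      matrix(rnorm(nLocations * N), nLocations, N), fs)
    plvR <- pairwisePLV(rest, spec, decimate = decimate)
    plvN <- pairwisePLV(null, spec, decimate = decimate)
    evc <- eigenvectorCentrality(plvR)
    feats <- buildFeatures(geom, evc)
    parc <- kmeansCosine(feats, k, seed = pairSeeds[i, 3L],
                         nstart = nstart)
    net <- buildRegionNetwork(plvR, plvN, parc, alpha = alpha,
                              seed = pairSeeds[i, 3L],
                              minPerms = minPerms, maxPerms = maxPerms,
                              stopTol = stopTol)
    mean(networkEdges(net)$significant)
  }, numeric(1))
  list(mean = mean(fractions), sd = sd(fractions), fractions = fractions,
       alpha = alpha, nPairs = nPairs)
}
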