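## Shared fixtures and independent oracles used across test files.

## Sinusoid bank: one row per (freq, phase), optional additive noise.
sinusoidSet <- function(freqs, phases = rep(0, length(freqs)),
                        duration = 10, fs = 250, noiseSd = 0,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  tvec <- (seq_len(n) - 1) / fs
  data <- t(mapply(function(f, p) sin(2 * pi * f * tvec + p),
                   freqs, phases))
  if (noiseSd > 0) data <- data + noiseSd * matrix(rnorm(length(data)),
                                                   nrow(data))
  makeTimeSeriesSet(data, fs)
}

## TRUE iff two labelings describe the same partition (up to relabeling).
samePartition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

## Independent EVC oracle: power iteration on the adjacency.
powerIterationEVC <- function(m, iters = 10000, tol = 1e-14) {
  v <- rep(1 / sqrt(nrow(m)), nrow(m))
  for (i in seq_len(iters)) {
    w <- m %*% v
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) break
    v <- w
  }
  as.vector(v)
}

## Exhaustive 2-cluster k-means oracle: enumerate every assignment of n
## points to two non-empty clusters, score with the same snap-to-member
## centroid convention, return the best labeling.
exhaustiveKmeans2 <- function(X) {
  n <- nrow(X)
  Xu <- X / sqrt(rowSums(X^2))
  cosd <- function(A, B) {
    d <- 1 - tcrossprod(A, B)
    d[d < 0] <- 0
    d
  }
  clusterCost <- function(members) {
    sub <- Xu[members, , drop = FALSE]
    mu <- colMeans(sub)
    if (sum(mu^2) == 0) return(Inf)
    snap <- members[which.min(cosd(sub, matrix(mu / sqrt(sum(mu^2)), 1)))]
    sum(cosd(sub, Xu[snap, , drop = FALSE]))
  }
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {   # point 1 always in cluster 1
    lab <- c(1L, as.integer(intToBits(code)[seq_len(n - 1)]) + 1L)
    if (!any(lab == 2L)) next
    cost <- clusterCost(which(lab == 1L)) + clusterCost(which(lab == 2L))
    if (is.null(best) || cost < best$cost) best <- list(labels = lab,
                                                        cost = cost)
  }
  best
}

## Exhaustive permutation-test oracle: all splits of the pooled values.
exhaustivePermTest <- function(x, y, alternative = "greater") {
  pooled <- c(x, y)
  nA <- length(x)
  obs <- mean(x) - mean(y)
  if (alternative == "two.sided") obs <- abs(obs)
  splits <- combn(length(pooled), nA)
  stats <- apply(splits, 2, function(idx)
    mean(pooled[idx]) - mean(pooled[-idx]))
  if (alternative == "two.sided") stats <- abs(stats)
  mean(stats >= obs - 1e-12)
}

## Small, valid Parcellation built directly from a label vector.
parcellationFromLabels <- function(labels) {
  labels <- as.integer(labels)
  k <- max(labels)
  stopifnot(all(sort(unique(labels)) == seq_len(k)))
  new("Parcellation", labels = labels,
      centroids = match(seq_len(k), labels), objective = 0,
      k = k, seed = 0L, iterations = 1L, converged = TRUE)
}

## Synthetic PLVMatrix wrapper around a plain symmetric matrix.
plvMatrixFromValues <- function(V, f0 = 10) {
  diag(V) <- 0
  V <- (V + t(V)) / 2
  new("PLVMatrix", values = V, f0 = f0, band = as.character(f0),
      nSamples = 100L, locationIds = paste0("loc", seq_len(nrow(V))))
}
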