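## Functionally defined regions: standardized (x, y, z, EVC) features,
## cosine distance, snap-to-datapoint k-means, dendrogram k selection.

#' Standardized clustering features from geometry and centrality
#'
#' Builds the L x 4 feature matrix whose columns are the (spherically
#' registered) surface coordinates x, y, z and the eigenvector
#' centrality score, each z-scored to zero mean and unit variance.
#' EVC is weighted equally with each spatial coordinate after
#' standardization.
#'
#' @param geom a [SurfaceGeometry-class] (faces may be empty).
#' @param evc a [CentralityVector-class] with matching length.
#' @param dropConstant if TRUE, zero-variance columns (e.g. the z
#'   coordinate of a planar grid) are dropped instead of raising an
#'   error.
#' @return numeric matrix with z-scored columns.
#' @export
buildFeatures <- function(geom, evc, dropConstant = FALSE) {
  stopifnot(is(geom, "SurfaceGeometry"), is(evc, "CentralityVector"))
  if (nrow(geom@vertices) != length(evc@scores))
    stop("geometry and centrality lengths differ")
  F <- cbind(geom@vertices, evc@scores)
  colnames(F) <- c("x", "y", "z", "evc")
  sds <- apply(F, 2L, sd)
  if (any(sds == 0)) {
    if (!dropConstant)
      stop(sprintf("constant column(s) %s: zero variance cannot be z-scored",
                   paste(colnames(F)[sds == 0], collapse = ", ")))
    F <- F[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(F, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Cosine distance between feature vectors
#'
#' `1 - (a . b) / (||a|| ||b||)`, in \[0, 2\]: 0 for parallel vectors,
#' 1 for orthogonal, 2 for antiparallel.
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @return scalar distance.
#' @export
cosineDistance <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm vector has no direction")
  1 - sum(a * b) / (na * nb)
}

## Row-normalize, rejecting zero rows.
rowUnit <- function(X) {
  n <- sqrt(rowSums(X^2))
  if (any(n == 0)) stop("zero-norm feature row")
  X / n
}

## Dense cosine-distance matrix between row sets (unit-normalized inputs).
cosineDistanceMatrix <- function(Xu, Yu = Xu) {
  D <- 1 - tcrossprod(Xu, Yu)
  D[D < 0] <- 0
  D
}

#' Cosine-distance k-means with snap-to-datapoint centroids
#'
#' Clusters feature rows into k groups minimizing the summed cosine
#' distance of members to their centroid.  The heuristic starts from k
#' random data points as centroids, then alternates (1) assigning each
#' point to its closest centroid and (2) recomputing each cluster's
#' mean and snapping the centroid to the member data point closest to
#' that mean (ties broken by lowest vertex index).  A snapped centroid
#' is accepted only when it does not increase the cluster's objective,
#' so the global objective is non-increasing and convergence (unchanged
#' assignments) is guaranteed within `maxIter` iterations.  Emptied
#' clusters are repaired by reseeding them with the point farthest from
#' its current centroid.
#'
#' @param features numeric L x d matrix (typically from
#'   [buildFeatures()]).
#' @param k number of clusters, 1 <= k <= L.
#' @param seed integer RNG seed controlling the restart sequence.
#' @param nstart number of random restarts; the lowest-objective
#'   solution is kept.
#' @param maxIter iteration cap per restart (default 1000).
#' @param init optional integer vector of k row indices used as the
#'   initial centroids of a single run (overrides `nstart`).
#' @return a [Parcellation-class].
#' @export
kmeansCosine <- function(features, k, seed = 1L, nstart = 10L,
                         maxIter = 1000L, init = NULL) {
  X <- as.matrix(features)
  L <- nrow(X)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k > L) stop("k cannot exceed the number of data points")
  Xu <- rowUnit(X)
  set.seed(as.integer(seed))
  inits <- if (!is.null(init)) {
    stopifnot(length(init) == k)
    list(as.integer(init))
  } else {
    lapply(seq_len(nstart), function(i) sample.int(L, k))
  }

  best <- NULL
  for (cent0 in inits) {
    run <- kmeansCosineOnce(Xu, k, cent0, maxIter)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  new("Parcellation", labels = best$labels, centroids = best$centroids,
      objective = best$objective, k = k, seed = as.integer(seed),
      iterations = best$iterations, converged = best$converged)
}

## One k-means run from given centroid indices on unit-normalized rows.
kmeansCosineOnce <- function(Xu, k, cent, maxIter) {
  L <- nrow(Xu)
  labels <- integer(L)
  obj <- Inf
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    D <- cosineDistanceMatrix(Xu, Xu[cent, , drop = FALSE])
    newLabels <- max.col(-D, ties.method = "first")
    ## centroids keep their own label (they are data points at distance 0)
    newLabels[cent] <- seq_len(k)
    ## empty-cluster repair: farthest point from its centroid becomes a
    ## singleton centroid
    repeat {
      counts <- tabulate(newLabels, nbins = k)
      empty <- which(counts == 0L)
      if (!length(empty)) break
      j <- empty[1L]
      dOwn <- D[cbind(seq_len(L), newLabels)]
      dOwn[cent] <- -Inf  # never steal a centroid
      dOwn[counts[newLabels] <= 1L] <- -Inf  # nor a singleton
      far <- which.max(dOwn)
      cent[j] <- far
      newLabels[far] <- j
      D[, j] <- cosineDistanceMatrix(Xu, Xu[far, , drop = FALSE])
    }
    ## update step: mean of members, snapped to nearest member (accepted
    ## only if the cluster objective does not increase)
    for (j in seq_len(k)) {
      members <- which(newLabels == j)
      mu <- colMeans(Xu[members, , drop = FALSE])
      nmu <- sqrt(sum(mu^2))
      if (nmu == 0) next  # degenerate antipodal cluster: keep centroid
      dToMu <- as.vector(cosineDistanceMatrix(
        Xu[members, , drop = FALSE], matrix(mu / nmu, 1L)))
      cand <- members[which.min(dToMu)]
      dCur <- sum(cosineDistanceMatrix(Xu[members, , drop = FALSE],
                                       Xu[cent[j], , drop = FALSE]))
      dNew <- sum(cosineDistanceMatrix(Xu[members, , drop = FALSE],
                                       Xu[cand, , drop = FALSE]))
      if (dNew <= dCur + 1e-12) cent[j] <- cand
    }
    newObj <- clusterObjective(Xu, newLabels, cent)
    if (newObj > obj + 1e-9)
      stop("internal error: k-means objective increased")  # nocov
    same <- identical(newLabels, labels)
    labels <- newLabels
    obj <- newObj
    if (same) { converged <- TRUE; break }
    if (iter >= maxIter) break
  }
  list(labels = labels, centroids = as.integer(cent), objective = obj,
       iterations = iter, converged = converged)
}

## Summed cosine distance of every point to its cluster's centroid point.
clusterObjective <- function(Xu, labels, cent) {
  D <- cosineDistanceMatrix(Xu, Xu[cent, , drop = FALSE])
  sum(D[cbind(seq_along(labels), labels)])
}

#' Dendrogram-guided selection of the number of regions
#'
#' Runs k-means once at `kMax` clusters, then agglomerates clusters by
#' average-linkage cosine distance between member feature rows (each
#' merge joins the closest pair; the merged pair's dissimilarity
#' `1 - similarity` is recorded).  The resulting profile of merge
#' dissimilarities versus remaining cluster count is the dendrogram used
#' to choose k: pick the largest k below the knee where dissimilarity
#' rises sharply.  With `kMax = nrow(features)` the procedure is exact
#' average-linkage agglomeration from singletons.
#'
#' @inheritParams kmeansCosine
#' @param kMax number of starting clusters (<= L).
#' @return data.frame with columns `k` (clusters remaining after the
#'   merge) and `height` (merge dissimilarity); empty when `kMax = 1`.
#' @export
dendrogramProfile <- function(features, kMax, seed = 1L, nstart = 10L) {
  X <- as.matrix(features)
  L <- nrow(X)
  kMax <- as.integer(kMax)
  if (kMax > L) stop("kMax cannot exceed the number of data points")
  if (kMax <= 1L)
    return(data.frame(k = integer(), height = numeric()))
  Xu <- rowUnit(X)
  labels <- if (kMax == L) seq_len(L) else
    parcelLabels(kmeansCosine(X, kMax, seed = seed, nstart = nstart))

  ## mean pairwise cosine distance between cluster members
  Dfull <- cosineDistanceMatrix(Xu)
  sizes <- tabulate(labels, nbins = kMax)
  Dc <- matrix(0, kMax, kMax)
  for (a in seq_len(kMax - 1L)) for (b in (a + 1L):kMax) {
    Dc[a, b] <- Dc[b, a] <-
      mean(Dfull[labels == a, labels == b, drop = FALSE])
  }
  alive <- rep(TRUE, kMax)
  heights <- numeric(kMax - 1L)
  for (step in seq_len(kMax - 1L)) {
    idx <- which(alive)
    sub <- Dc[idx, idx, drop = FALSE]
    diag(sub) <- Inf
    m <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    a <- idx[m[1L]]; b <- idx[m[2L]]
    heights[step] <- Dc[a, b]
    ## Lance-Williams average-linkage update: merge b into a
    for (o in idx[!idx %in% c(a, b)]) {
      Dc[a, o] <- Dc[o, a] <-
        (sizes[a] * Dc[a, o] + sizes[b] * Dc[b, o]) / (sizes[a] + sizes[b])
    }
    sizes[a] <- sizes[a] + sizes[b]
    alive[b] <- FALSE
  }
  data.frame(k = (kMax - 1L):1L, height = heights)
}

#' Spatial contiguity of a parcellation
#'
#' Counts the connected components of each cluster on the mesh
#' face-adjacency graph.  Spatially smooth regions have one component;
#' values above 1 flag disjoint functional areas.
#'
#' @param parc a [Parcellation-class].
#' @param geom a [SurfaceGeometry-class] with a face list.
#' @return integer vector of per-cluster component counts (length k).
#' @export
contiguityReport <- function(parc, geom) {
  stopifnot(is(parc, "Parcellation"), is(geom, "SurfaceGeometry"))
  if (!nrow(geom@faces)) stop("geometry has no faces")
  ed <- rbind(geom@faces[, c(1L, 2L)], geom@faces[, c(2L, 3L)],
              geom@faces[, c(1L, 3L)])
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < nrow(geom@vertices))
    g <- igraph::add_vertices(g, nrow(geom@vertices) - igraph::vcount(g))
  labels <- parcelLabels(parc)
  vapply(seq_len(parc@k), function(j) {
    sub <- igraph::induced_subgraph(g, which(labels == j))
    as.integer(igraph::components(sub)$no)
  }, integer(1))
}
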