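## Eigenvector centrality of the weighted phase-locking graph.

#' Eigenvector centrality of a PLV adjacency matrix
#'
#' Computes the first singular vector of the symmetric, non-negative,
#' zero-diagonal adjacency (equivalently the leading eigenvector), the
#' relative importance of each dipole in the phase-locking graph.  The
#' vector is oriented so the largest-magnitude entry is positive
#' (Perron-Frobenius orientation), entries below 1e-12 in magnitude are
#' clamped to zero for determinism across linear-algebra backends, and
#' the result has unit Euclidean norm.
#'
#' @param adj a [PLVMatrix-class] or a plain symmetric non-negative
#'   matrix with zero diagonal.
#' @return a [CentralityVector-class].
#' @examples
#' a <- matrix(1, 4, 4); diag(a) <- 0
#' centralityScores(eigenvectorCentrality(a))  # all 1/2 by symmetry
#' @export
eigenvectorCentrality <- function(adj) {
  if (is(adj, "PLVMatrix")) {
    m <- adj@values
    ids <- adj@locationIds
  } else {
    m <- adj
    ids <- if (!is.null(rownames(m))) rownames(m)
           else paste0("loc", seq_len(nrow(m)))
  }
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("adjacency must be symmetric")
  if (any(m < 0)) stop("adjacency must be non-negative")
  if (any(diag(m) != 0)) stop("adjacency diagonal must be zero")
  if (all(m == 0))
    stop("all-zero adjacency: centrality undefined")
  ## For a symmetric non-negative adjacency the SVD coincides with the
  ## eigendecomposition up to sign, but on (near-)bipartite graphs the
  ## leading singular subspace is degenerate (eigenvalues +r and -r give
  ## the same singular value); the symmetric eigensolver resolves the
  ## Perron vector unambiguously.
  v <- eigen(m, symmetric = TRUE)$vectors[, 1L]
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  v[abs(v) < 1e-12] <- 0
  v[v < 0] <- 0  # residual numerical negatives on disconnected parts
  v <- v / sqrt(sum(v^2))
  new("CentralityVector", scores = v, locationIds = ids)
}

#' Average PLV adjacencies across subjects
#'
#' Entrywise mean of per-subject adjacency matrices in a common space
#' (identical dimension and vertex correspondence), preserving symmetry
#' and the zero diagonal.  The package's default subject aggregation is
#' adjacency-first: average the matrices, then compute one centrality
#' vector (see [subjectCentrality()]).
#'
#' @param matrices list of [PLVMatrix-class] objects with identical
#'   location ordering.
#' @return a [PLVMatrix-class].
#' @export
averageAdjacency <- function(matrices) {
  if (!length(matrices)) stop("need at least one matrix")
  stopifnot(all(vapply(matrices, is, logical(1), "PLVMatrix")))
  ids <- matrices[[1L]]@locationIds
  n <- nrow(matrices[[1L]]@values)
  for (m in matrices) {
    if (nrow(m@values) != n) stop("matrix dimensions differ")
    if (!identical(m@locationIds, ids))
      stop("vertex correspondence differs between matrices")
  }
  V <- Reduce(`+`, lapply(matrices, slot, "values")) / length(matrices)
  V <- (V + t(V)) / 2
  diag(V) <- 0
  new("PLVMatrix", values = V, f0 = matrices[[1L]]@f0,
      band = matrices[[1L]]@band, nSamples = matrices[[1L]]@nSamples,
      locationIds = ids)
}

#' Group-level centrality from per-subject adjacencies
#'
#' Two readings of cross-subject aggregation are supported:
#' `method = "adjacency"` (default) averages the adjacency matrices and
#' computes a single centrality vector; `method = "centrality"` computes
#' per-subject centrality vectors and averages those (renormalized).
#'
#' @param matrices list of [PLVMatrix-class] objects.
#' @param method "adjacency" or "centrality".
#' @return a [CentralityVector-class].
#' @export
subjectCentrality <- function(matrices,
                              method = c("adjacency", "centrality")) {
  method <- match.arg(method)
  if (method == "adjacency")
    return(eigenvectorCentrality(averageAdjacency(matrices)))
  vs <- vapply(matrices, function(m) eigenvectorCentrality(m)@scores,
               numeric(nrow(matrices[[1L]]@values)))
  v <- rowMeans(vs)
  v <- v / sqrt(sum(v^2))
  new("CentralityVector", scores = v,
      locationIds = matrices[[1L]]@locationIds)
}
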