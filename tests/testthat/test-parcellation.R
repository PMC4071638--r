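test_that("feature building z-scores all four columns", {
  set.seed(12)
  geom <- makeSurfaceGeometry(fibonacciSphere(50))
  evc <- eigenvectorCentrality(plvMatrixFromValues(matrix(runif(2500), 50)))
  F <- buildFeatures(geom, evc)
  expect_identical(dim(F), c(50L, 4L))
  expect_equal(unname(colMeans(F)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(F, 2, var)), rep(1, 4), tolerance = 1e-8)
  ## mismatched lengths and constant columns are rejected
  expect_error(buildFeatures(makeSurfaceGeometry(fibonacciSphere(49)), evc),
               "lengths differ")
  flat <- makeSurfaceGeometry(cbind(rnorm(50), rnorm(50), 0))
  expect_error(buildFeatures(flat, evc), "constant")
  expect_identical(ncol(buildFeatures(flat, evc, dropConstant = TRUE)), 3L)
})

test_that("spatially symmetric vertices give mirrored feature rows", {
  v <- rbind(c(1, 2, -1), c(-1, -2, 1), c(3, 0, 2), c(-3, 0, -2))
  geom <- makeSurfaceGeometry(v)
  evc <- new("CentralityVector", scores = rep(0.5, 4),
             locationIds = paste0("v", 1:4))
  F <- buildFeatures(geom, evc, dropConstant = TRUE)  # evc is constant
  expect_equal(F[1, ], -F[2, ], tolerance = 1e-12)
  expect_equal(F[3, ], -F[4, ], tolerance = 1e-12)
})

test_that("cosine distance has its three landmark values", {
  expect_equal(cosineDistance(c(1, 2, 3), c(2, 4, 6)), 0)
  expect_equal(cosineDistance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosineDistance(c(1, 2), c(-1, -2)), 2)
  expect_error(cosineDistance(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("k-means recovers well-separated antipodal blobs exactly", {
  set.seed(31)
  blob <- function(center, n) {
    x <- matrix(rnorm(n * 3, sd = 0.05), n) +
      matrix(center, n, 3, byrow = TRUE)
    x / sqrt(rowSums(x^2))
  }
  X <- rbind(blob(c(0, 0, 1), 5), blob(c(0, 0, -1), 5))
  truth <- rep(1:2, each = 5)
  parc <- kmeansCosine(X, 2, seed = 1)
  expect_true(samePartition(parcelLabels(parc), truth))
  ## exhaustive assignment search oracle agrees
  oracle <- exhaustiveKmeans2(X)
  expect_true(samePartition(parcelLabels(parc), oracle$labels))
  expect_equal(parc@objective, oracle$cost, tolerance = 1e-10)
})

test_that("k-means structural invariants hold", {
  set.seed(32)
  X <- matrix(rnorm(120), 30, 4)
  parc <- kmeansCosine(X, 6, seed = 2)
  labels <- parcelLabels(parc)
  expect_identical(sort(unique(labels)), 1:6)        # no empty clusters
  expect_identical(labels[parcelCentroids(parc)], 1:6)
  expect_lte(parc@iterations, 1000L)
  expect_true(parc@converged)
  ## determinism given (features, k, seed)
  parc2 <- kmeansCosine(X, 6, seed = 2)
  expect_identical(parcelLabels(parc2), labels)
  ## k = L: every point its own cluster, objective zero
  full <- kmeansCosine(X, 30, seed = 1, nstart = 1)
  expect_equal(full@objective, 0)
  expect_identical(sort(unique(parcelLabels(full))), 1:30)
  expect_error(kmeansCosine(X, 31), "exceed")
  expect_error(kmeansCosine(X, 0), "at least 1")
})

test_that("k-means restarted at a converged solution is a fixed point", {
  set.seed(33)
  X <- matrix(rnorm(100), 25, 4)
  parc <- kmeansCosine(X, 4, seed = 9)
  again <- kmeansCosine(X, 4, seed = 9, init = parcelCentroids(parc))
  expect_identical(parcelLabels(again), parcelLabels(parc))
  expect_equal(again@objective, parc@objective, tolerance = 1e-12)
  expect_lte(again@iterations, 2L)
})

test_that("parcellation is invariant to an axis-permuting rotation", {
  set.seed(34)
  geom <- makeSurfaceGeometry(fibonacciSphere(60))
  evc <- eigenvectorCentrality(
    plvMatrixFromValues(matrix(runif(3600), 60)))
  F1 <- buildFeatures(geom, evc)
  rot <- geom
  rot@vertices <- cbind(geom@vertices[, 2], -geom@vertices[, 1],
                        geom@vertices[, 3])
  F2 <- buildFeatures(rot, evc)
  p1 <- kmeansCosine(F1, 8, seed = 5)
  p2 <- kmeansCosine(F2, 8, seed = 5)
  expect_true(samePartition(parcelLabels(p1), parcelLabels(p2)))
})

test_that("dendrogram profile matches average-linkage agglomeration", {
  set.seed(35)
  X <- matrix(rnorm(80), 20, 4)
  prof <- dendrogramProfile(X, kMax = 20)
  ## independent oracle: hclust average linkage on the same distances
  Xu <- X / sqrt(rowSums(X^2))
  D <- 1 - tcrossprod(Xu)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  expect_equal(prof$height, hc$height, tolerance = 1e-8)
  ## merge dissimilarities are non-decreasing as k decreases
  expect_true(all(diff(prof$height) >= -1e-10))
  expect_identical(prof$k, 19:1)
})

test_that("dendrogram endpoints behave", {
  set.seed(36)
  ## two exactly duplicated points merge at dissimilarity zero
  X <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0))
  prof <- dendrogramProfile(X, kMax = 3)
  expect_equal(prof$height[1], 0, tolerance = 1e-12)
  ## kMax = 1 gives an empty profile
  expect_identical(nrow(dendrogramProfile(X, kMax = 1)), 0L)
})

test_that("contiguity report counts connected components per cluster", {
  mesh <- makeSphereMesh(5, 10)
  whole <- parcellationFromLabels(rep(1L, nrow(mesh@vertices)))
  expect_identical(contiguityReport(whole, mesh), 1L)
  ## a cluster split across two grid corners has two components
  grid <- makeGridGeometry(6, 6)
  labels <- rep(1L, 36)
  labels[c(1, 36)] <- 2L           # two opposite corner cells
  parc <- parcellationFromLabels(labels)
  rep2 <- contiguityReport(parc, grid)
  expect_identical(rep2, c(1L, 2L))
  expect_length(rep2, parc@k)
})
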