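test_that("identity gain with unit covariances halves the input", {
  m <- buildInverse(diag(3), diag(3), diag(3), snr = 1)
  expect_equal(m@W, 0.5 * diag(3), tolerance = 1e-12)
  expect_identical(m@lambda2, 1)
})

test_that("the inverse approaches A^-1 as regularization vanishes", {
  set.seed(51)
  A <- matrix(rnorm(16), 4) + 4 * diag(4)
  m <- buildInverse(A, diag(4), diag(4), snr = 1e10)
  expect_lt(norm(m@W - solve(A), "F") / norm(solve(A), "F"), 1e-6)
})

test_that("the operator solves the weighted regularized least squares", {
  set.seed(52)
  nSens <- 5; nSrc <- 8
  A <- matrix(rnorm(nSens * nSrc), nSens)
  Rm <- crossprod(matrix(rnorm(nSrc * nSrc), nSrc)) + diag(nSrc)
  Cm <- crossprod(matrix(rnorm(nSens * nSens), nSens)) + diag(nSens)
  snr <- 2
  m <- buildInverse(A, Rm, Cm, snr)
  x <- rnorm(nSens)
  ## normal-equations oracle: (A' C^-1 A + lambda2 R^-1)^-1 A' C^-1 x
  lam2 <- 1 / snr
  oracle <- solve(t(A) %*% solve(Cm, A) + lam2 * solve(Rm),
                  t(A) %*% solve(Cm, x))
  expect_equal(as.vector(m@W %*% x), as.vector(oracle),
               tolerance = 1e-8)
})

test_that("the defining identity holds for random SPD covariances", {
  set.seed(53)
  for (i in 1:5) {
    A <- matrix(rnorm(6 * 10), 6)
    Rm <- crossprod(matrix(rnorm(100), 10)) + 0.5 * diag(10)
    Cm <- crossprod(matrix(rnorm(36), 6)) + 0.5 * diag(6)
    m <- buildInverse(A, Rm, Cm, snr = runif(1, 0.1, 10))
    G <- A %*% Rm %*% t(A) + m@lambda2 * Cm
    resid <- norm(m@W %*% G - Rm %*% t(A), "F") /
      norm(Rm %*% t(A), "F")
    expect_lt(resid, 1e-8)
  }
  expect_error(buildInverse(matrix(1, 2, 3), diag(2), diag(2), 1),
               "dimension")
})

test_that("depth weighting scales R by the gain column norm power", {
  ## two radial sources, one with half-norm gain: R ratio 2^1.6
  sensors <- fibonacciSphere(20, 1.5)
  sources <- rbind(c(0, 0, 1), c(0, 0, 0.5))
  A3 <- syntheticGain(sources, sensors)
  normals <- rbind(c(0, 0, 1), c(0, 0, 1))
  dw <- depthOrientationWeighting(A3, normals)
  ## direct arithmetic oracle from the weighting rule
  wNorm <- vapply(1:2, function(j) {
    Gj <- A3[, j, ]
    gn <- Gj %*% c(0, 0, 1)
    Gt <- Gj - gn %*% t(c(0, 0, 1))
    sqrt(sum((gn %*% t(c(0, 0, 1)) + 0.4 * Gt)^2))
  }, numeric(1))
  expect_equal(diag(dw$R), wNorm^(-1.6), tolerance = 1e-10)
  expect_equal(dw$R[2, 2] / dw$R[1, 1], (wNorm[1] / wNorm[2])^1.6,
               tolerance = 1e-10)
})

test_that("tangential weighting is a no-op for purely normal gains", {
  ## construct a gain that is already aligned with the normals
  nSens <- 10
  A3 <- array(0, c(nSens, 2, 3))
  A3[, 1, 3] <- rnorm(nSens)       # source 1 normal = z
  A3[, 2, 1] <- rnorm(nSens)       # source 2 normal = x
  normals <- rbind(c(0, 0, 1), c(1, 0, 0))
  dw <- depthOrientationWeighting(A3, normals)
  expect_equal(dw$A[, 1], A3[, 1, 3], tolerance = 1e-12)
  expect_equal(dw$A[, 2], A3[, 2, 1], tolerance = 1e-12)
})

test_that("applying the inverse is linear and maps zero to zero", {
  set.seed(54)
  A <- matrix(rnorm(12), 3)
  m <- buildInverse(A, diag(4), diag(3), snr = 1)
  z <- applyInverse(m, makeTimeSeriesSet(matrix(0, 3, 10), 100))
  expect_identical(tsData(z), matrix(0, 4, 10))
  a <- matrix(rnorm(30), 3); b <- matrix(rnorm(30), 3)
  ya <- tsData(applyInverse(m, makeTimeSeriesSet(a, 100)))
  yb <- tsData(applyInverse(m, makeTimeSeriesSet(b, 100)))
  yab <- tsData(applyInverse(m, makeTimeSeriesSet(a + b, 100)))
  expect_equal(yab, ya + yb, tolerance = 1e-12)
  expect_error(applyInverse(m, makeTimeSeriesSet(matrix(0, 5, 10), 100)),
               "dimension")
})

test_that("forward-then-inverse recovers a dipole at or near its vertex", {
  mesh <- makeSphereMesh(6, 12)
  sim <- simulateDipolePair(
    dipolePairScenario(distance = 1.4, amplitude = 1, noiseScale = 1e-4,
                       duration = 4, seed = 3),
    mesh, snr = 100)
  power <- rowMeans(tsData(sim$series)^2)
  V <- mesh@vertices
  for (v in sim$truth) {
    d <- sqrt(rowSums(sweep(V, 2, V[v, ])^2))
    neighborhood <- which(d <= sort(d)[7])   # vertex + ~6 neighbors
    expect_true(which.max(power * (d <= max(d[neighborhood]))) %in%
                  neighborhood || which.max(power) %in% neighborhood)
  }
  ## reconstruction point spread: neighbors of an active dipole lock
  ph <- instantaneousPhase(sim$series, makeWaveletSpec(10))
  P <- phaseValues(ph)
  v1 <- sim$truth[1]
  d1 <- sqrt(rowSums(sweep(V, 2, V[v1, ])^2))
  nb <- setdiff(order(d1)[2:4], sim$truth)
  for (n in nb) expect_gt(plv(P[v1, ], P[n, ]), 0.5)
})

test_that("dipole-pair simulation is deterministic and checks distance", {
  mesh <- makeSphereMesh(6, 12)
  scn <- dipolePairScenario(1.4, 0.5, noiseScale = 0.5, duration = 2,
                            seed = 8)
  s1 <- simulateDipolePair(scn, mesh)
  s2 <- simulateDipolePair(scn, mesh)
  expect_identical(tsData(s1$series), tsData(s2$series))
  expect_error(simulateDipolePair(
    dipolePairScenario(7, 0.5, duration = 2), mesh), "unattainable")
})
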