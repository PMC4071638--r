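test_that("grid simulation is deterministic and validates its blocks", {
  scn <- gridScenario(c(12L, 12L), blockSize = 3L, duration = 2,
                      seed = 61)
  a <- simulateGrid(scn)
  b <- simulateGrid(scn)
  expect_identical(tsData(a$series), tsData(b$series))
  expect_identical(dim(tsData(a$series)), c(144L, 500L))
  expect_length(a$truth$blockCells[[1]], 9L)
  expect_error(gridScenario(c(12L, 12L), blockSize = 3L,
                            blockCorners = list(c(2, 2), c(3, 3))),
               "overlap")
  expect_error(gridScenario(c(12L, 12L), blockSize = 6L,
                            blockCorners = list(c(1, 1), c(9, 9))),
               "fit")
})

test_that("noiseless equal-frequency blocks lock perfectly", {
  ## huge SNR approximates the noiseless limit
  scn <- gridScenario(c(8L, 8L), blockSize = 2L, w1 = 10, snrDb = 80,
                      duration = 4, seed = 62)
  sim <- simulateGrid(scn)
  M <- plvValues(pairwisePLV(sim$series, makeWaveletSpec(10)))
  cross <- M[sim$truth$blockCells[[1]], sim$truth$blockCells[[2]]]
  expect_true(all(cross > 0.999))
})

test_that("zero amplitude and off-frequency generators stay at the floor", {
  base <- gridScenario(c(8L, 8L), blockSize = 2L, w1 = 25,
                       amplitudeMultiplier = 0, duration = 8, seed = 63)
  sim <- simulateGrid(base)
  M <- plvValues(pairwisePLV(sim$series, makeWaveletSpec(25)))
  floor <- stats::quantile(M[upper.tri(M)], 0.999)
  cross0 <- M[sim$truth$centers[1], sim$truth$centers[2]]
  expect_lt(cross0, floor + 0.05)
  ## w2 = 1 Hz analyzed at 25 Hz: indistinguishable from noise
  off <- gridScenario(c(8L, 8L), blockSize = 2L, w1 = 25, w2 = 1,
                      snrDb = 0, duration = 8, seed = 63)
  simOff <- simulateGrid(off)
  Moff <- plvValues(pairwisePLV(simOff$series, makeWaveletSpec(25)))
  crossOff <- mean(Moff[simOff$truth$blockCells[[1]],
                        simOff$truth$blockCells[[2]]])
  expect_lt(crossOff, 0.2)
})

test_that("an additive low-frequency modulator is rejected by the wavelet", {
  clean <- gridScenario(c(8L, 8L), blockSize = 2L, w1 = 25, snrDb = 0,
                        duration = 8, seed = 64)
  modded <- gridScenario(c(8L, 8L), blockSize = 2L, w1 = 25, snrDb = 0,
                         modFreq = 1, duration = 8, seed = 64)
  s <- makeWaveletSpec(25)
  m1 <- plvValues(pairwisePLV(simulateGrid(clean)$series, s))
  m2 <- plvValues(pairwisePLV(simulateGrid(modded)$series, s))
  tr <- simulateGrid(clean)$truth
  c1 <- mean(m1[tr$blockCells[[1]], tr$blockCells[[2]]])
  c2 <- mean(m2[tr$blockCells[[1]], tr$blockCells[[2]]])
  expect_lt(abs(c1 - c2), 0.05)
})

test_that("FWHM recovers the analytic Gaussian half-max radius", {
  geom <- makeSurfaceGeometry(cbind(seq(0, 10, length.out = 200), 0, 0))
  d <- abs(geom@vertices[, 1] - geom@vertices[1, 1])
  for (sigma in c(1, 2.5)) {
    V <- outer(rep(0, 200), rep(0, 200))
    V[1, ] <- V[, 1] <- exp(-d^2 / (2 * sigma^2))
    fw <- computeFwhm(plvMatrixFromValues(V), geom, 1, nBins = 40)
    expect_lt(abs(fw$radius - sigma * sqrt(2 * log(2))), fw$binWidth)
  }
})

test_that("FWHM handles linear and flat profiles as specified", {
  geom <- makeSurfaceGeometry(cbind(seq(0, 8, length.out = 150), 0, 0))
  d <- abs(geom@vertices[, 1])
  lin <- matrix(0, 150, 150)
  lin[1, ] <- lin[, 1] <- pmax(0, 1 - d / 8)
  fw <- computeFwhm(plvMatrixFromValues(lin), geom, 1, nBins = 40)
  expect_lt(abs(fw$radius - 4), 2 * fw$binWidth)
  flat <- matrix(0.6, 150, 150)
  expect_error(computeFwhm(plvMatrixFromValues(flat), geom, 1),
               "flat profile")
})

test_that("ROC endpoints: perfect separation, inversion and shuffling", {
  set.seed(65)
  sep <- rocFromScores(c(rnorm(50, 8), rnorm(50)),
                       rep(c(TRUE, FALSE), each = 50))
  expect_equal(sep$auc, 1)
  scores <- rnorm(100); labels <- rep(c(TRUE, FALSE), 50)
  fwd <- rocFromScores(scores, labels)
  inv <- rocFromScores(-scores, labels)
  expect_equal(inv$auc, 1 - fwd$auc, tolerance = 1e-10)
  shuf <- rocFromScores(rnorm(200), sample(rep(c(TRUE, FALSE), 100)))
  expect_lt(abs(shuf$auc - 0.5), 0.15)
  expect_error(rocFromScores(rnorm(5), rep(TRUE, 5)), "single-class")
  ## the assembled curve is monotone with anchored endpoints
  expect_true(all(diff(fwd$points$fpr) >= 0))
  expect_true(all(diff(fwd$points$tpr) >= 0))
})

test_that("roc analysis agrees with an independent AUC implementation", {
  skip_if_not_installed("pROC")
  set.seed(66)
  scores <- rnorm(120, mean = rep(c(1, 0), 60))
  labels <- rep(c(TRUE, FALSE), 60)
  ours <- rocFromScores(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                           quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("detection scoring covers the degenerate cases", {
  parc <- parcellationFromLabels(c(1, 1, 2, 2, 3, 3, 4, 4))
  truth <- c(1L, 3L)   # clusters 1 and 2
  mkNet <- function(sig) {
    pairs <- t(combn(4, 2))
    new("RegionNetwork", k = 4L,
        edges = data.frame(regionA = pairs[, 1], regionB = pairs[, 2],
                           observed = 1, p = ifelse(sig, 0.001, 0.9),
                           nPerms = 5000L, significant = sig),
        alpha = 0.05)
  }
  ## only the truth pair connected: TP, zero FPR
  sig <- c(TRUE, rep(FALSE, 5))       # pair (1,2) first in combn order
  sc <- scoreDetection(mkNet(sig), parc, truth)
  expect_true(sc$tpDipole)
  expect_identical(sc$fpr, 0)
  ## nothing significant: no TP, no FP
  sc0 <- scoreDetection(mkNet(rep(FALSE, 6)), parc, truth)
  expect_false(sc0$tpDipole)
  expect_identical(sc0$fpr, 0)
  ## everything significant: FPR = 1 under the stated denominator
  sc1 <- scoreDetection(mkNet(rep(TRUE, 6)), parc, truth)
  expect_true(sc1$tpDipole)
  expect_identical(sc1$fpr, 1)
})

test_that("the battery emits one row per condition-setting-repetition", {
  b <- perturbationBattery(
    reps = 2, seed = 67, gridDims = c(10L, 10L), blockSize = 3L,
    duration = 2, k = 6L, minPerms = 100L, maxPerms = 100L,
    maxEdges = 50L, decimate = 4L, nstart = 1L)
  expect_identical(nrow(b), 32L)     # 4 conditions x 4 settings x 2
  expect_setequal(unique(b$condition),
                  c("snr", "modulation", "jitter", "frequency"))
  expect_true(all(table(b$condition) == 8L))
  agg <- batteryTPR(b)
  expect_identical(nrow(agg), 16L)
  expect_true(all(agg$tpr >= 0 & agg$tpr <= 1))
})

test_that("amplitude calibration hits a requested PLV target", {
  mesh <- makeSphereMesh(5, 10)
  cal <- calibrateDipoleAmplitude(0.6, distance = 1.4, geom = mesh,
                                  noiseScale = 1, duration = 8,
                                  seed = 68, tol = 0.02,
                                  bracket = c(1e-4, 10))
  expect_lt(abs(cal$plv - 0.6), 0.02 + 1e-9)
})
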