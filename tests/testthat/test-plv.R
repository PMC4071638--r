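test_that("PLV limits: constant offset gives 1, alternating pi gives 0", {
  th <- runif(200, -pi, pi)
  expect_equal(plv(th, th + 0.7), 1, tolerance = 1e-12)
  ## phase differences alternating 0, pi over an even length cancel
  th2 <- th + rep(c(0, pi), 100)
  expect_equal(plv(th, th2), 0, tolerance = 1e-12)
  expect_error(plv(1:3, 1:4), "equal length")
  expect_error(plv(numeric(), numeric()), "empty")
})

test_that("PLV is exactly symmetric and bounded for arbitrary inputs", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:50, 1)
    a <- runif(n, -pi, pi); b <- runif(n, -pi, pi)
    expect_identical(plv(a, b), plv(b, a))
    expect_gte(plv(a, b), 0)
    expect_lte(plv(a, b), 1)
  }
})

test_that("random-phase PLV matches the resultant-length Monte-Carlo value", {
  ## iid uniform phases, length N: E[PLV] ~ sqrt(pi / (4 N))
  set.seed(7)
  n <- 100
  draws <- replicate(1e4, plv(runif(n, -pi, pi), runif(n, -pi, pi)))
  expect_equal(mean(draws), sqrt(pi / (4 * n)), tolerance = 0.02)
})

test_that("PLV is invariant to the amplitude of either signal", {
  x <- sinusoidSet(c(10, 10), phases = c(0, 1), duration = 6,
                   noiseSd = 0.5, seed = 3)
  s <- makeWaveletSpec(10)
  base <- plvValues(pairwisePLV(x, s))[1, 2]
  for (scl in c(1e-4, 0.1, 37, 1e5)) {
    xs <- makeTimeSeriesSet(rbind(tsData(x)[1, ] * scl, tsData(x)[2, ]),
                            samplingRate(x))
    expect_lt(abs(plvValues(pairwisePLV(xs, s))[1, 2] - base), 1e-6)
  }
})

test_that("pairwisePLV equals the brute-force loop over all pairs", {
  x <- sinusoidSet(c(8, 10, 10, 12, 25), phases = c(0, 0, 1, 2, 0),
                   duration = 5, noiseSd = 1, seed = 9)
  s <- makeWaveletSpec(10)
  M <- plvValues(pairwisePLV(x, s))
  P <- phaseValues(instantaneousPhase(x, s))
  L <- nrow(P)
  expect_identical(dim(M), c(L, L))
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    expect_equal(M[i, j], plv(P[i, ], P[j, ]), tolerance = 1e-10)
    expect_identical(M[i, j], M[j, i])
  }
  expect_identical(diag(M), rep(0, L))
  ## two identical rows lock perfectly
  xx <- makeTimeSeriesSet(tsData(x)[c(1, 1, 3), ], samplingRate(x))
  expect_equal(plvValues(pairwisePLV(xx, s))[1, 2], 1, tolerance = 1e-9)
})

test_that("pairwisePLV is independent of the block size", {
  x <- sinusoidSet(rep(10, 7), phases = runif(7, -pi, pi), duration = 4,
                   noiseSd = 1, seed = 5)
  s <- makeWaveletSpec(10)
  ref <- plvValues(pairwisePLV(x, s, blockSize = 128))
  for (bs in c(1, 2, 3, 7)) {
    expect_equal(plvValues(pairwisePLV(x, s, blockSize = bs)), ref,
                 tolerance = 1e-12)
  }
})

test_that("independent noise rows stay near the PLV noise floor", {
  set.seed(21)
  x <- makeTimeSeriesSet(matrix(rnorm(6 * 3e4), 6), fs = 250)
  M <- plvValues(pairwisePLV(x, makeWaveletSpec(10)))
  expect_lt(max(M[upper.tri(M)]), 0.1)
})

test_that("band averaging preserves structure and averages entrywise", {
  x <- sinusoidSet(c(9, 10, 11), duration = 4, noiseSd = 1, seed = 2)
  mats <- frequencyGridPLV(x, freqs = 8:13)
  expect_length(mats, 6L)
  avg <- bandAverage(mats, band = "8:13")
  manual <- Reduce(`+`, lapply(mats, plvValues)) / 6
  expect_equal(plvValues(avg), manual, tolerance = 1e-12)
  expect_identical(diag(plvValues(avg)), rep(0, 3))
  ## single matrix is the identity operation
  expect_equal(plvValues(bandAverage(mats[1])), plvValues(mats[[1]]))
  ## all-ones and all-zeros average to one half
  ones <- plvMatrixFromValues(matrix(1, 4, 4))
  zeros <- plvMatrixFromValues(matrix(0, 4, 4))
  half <- plvValues(bandAverage(list(ones, zeros)))
  expect_equal(half[upper.tri(half)], rep(0.5, 6))
  ## shape/ordering mismatches are rejected
  expect_error(bandAverage(list(ones, plvMatrixFromValues(matrix(0, 3, 3)))),
               "dimensions")
})
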