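test_that("edge populations contain exactly the cross-region values", {
  set.seed(41)
  V <- plvMatrixFromValues(matrix(runif(100), 10))
  parc <- parcellationFromLabels(c(1, 1, 1, 2, 2, 2, 2, 3, 3, 3))
  pop <- collectEdgeValues(V, parc, 1, 2)
  expect_length(pop$values, 12L)              # |A| * |B|
  expect_setequal(pop$values,
                  as.vector(plvValues(V)[1:3, 4:7]))
  ## pooling over two subjects doubles the population
  pop2 <- collectEdgeValues(list(V, V), parc, 1, 2)
  expect_length(pop2$values, 24L)
  expect_error(collectEdgeValues(V, parc, 2, 2), "self-comparison")
})

test_that("permutation test endpoints behave", {
  set.seed(42)
  x <- runif(20)
  ## a population against an identical copy: observed stat 0, ns
  t0 <- permutationTest(x, x, seed = 1)
  expect_identical(t0$observed, 0)
  expect_false(t0$significant)
  ## total separation: smallest attainable p, significant
  hi <- runif(15) + 10; lo <- runif(15)
  t1 <- permutationTest(hi, lo, seed = 2)
  expect_equal(t1$p, 1 / (t1$nPerms + 1))
  expect_true(t1$significant)
  expect_gte(t1$nPerms, 5000)
  expect_error(permutationTest(numeric(), lo), "non-empty")
  expect_error(permutationTest(hi, lo, alpha = 0), "alpha")
})

test_that("Monte-Carlo p matches exhaustive enumeration on tiny data", {
  set.seed(43)
  for (rep in 1:5) {
    x <- rnorm(3, mean = rep * 0.3)
    y <- rnorm(3)
    exact <- exhaustivePermTest(x, y)
    mc <- permutationTest(x, y, seed = rep, minPerms = 5000)
    expect_lt(abs(mc$p - exact), 0.02)
  }
  ## two-sided variant against its own enumeration
  x <- c(0.1, 0.5, 0.9, 0.2); y <- c(0.4, 0.6, 0.3, 0.8)
  exact2 <- exhaustivePermTest(x, y, "two.sided")
  mc2 <- permutationTest(x, y, seed = 99, alternative = "two.sided")
  expect_lt(abs(mc2$p - exact2), 0.02)
})

test_that("exhaustive p is invariant to relabeling within populations", {
  set.seed(44)
  x <- rnorm(4); y <- rnorm(4)
  expect_identical(exhaustivePermTest(x, y),
                   exhaustivePermTest(sample(x), sample(y)))
})

test_that("null p-values are approximately uniform", {
  set.seed(45)
  ps <- replicate(200, {
    x <- rnorm(15); y <- rnorm(15)
    permutationTest(x, y, minPerms = 1000, maxPerms = 1000)$p
  })
  ## p is a discrete (b+1)/(m+1) estimator, so ties are expected
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("doubling the permutation budget barely moves p", {
  set.seed(46)
  x <- rnorm(25, 0.25); y <- rnorm(25)
  p1 <- permutationTest(x, y, minPerms = 5000, maxPerms = 5000,
                        seed = 7)$p
  p2 <- permutationTest(x, y, minPerms = 10000, maxPerms = 10000,
                        seed = 7)$p
  expect_lt(abs(p1 - p2), 0.01)
})

test_that("region networks test every unordered pair once", {
  set.seed(47)
  L <- 120
  V <- plvMatrixFromValues(matrix(runif(L * L), L))
  labels <- rep(1:40, 3)
  parc <- parcellationFromLabels(labels)
  net <- buildRegionNetwork(V, V, parc, seed = 3, minPerms = 100,
                            maxPerms = 100)
  edges <- networkEdges(net)
  expect_identical(nrow(edges), 780L)          # 40 * 39 / 2
  expect_true(all(edges$regionA < edges$regionB))
  expect_identical(anyDuplicated(paste(edges$regionA, edges$regionB)), 0L)
  ## degenerate alpha = 1: every pair significant
  net1 <- buildRegionNetwork(V, V, parc, alpha = 1, seed = 3,
                             minPerms = 100, maxPerms = 100)
  expect_true(all(networkEdges(net1)$significant))
  ## determinism under the master seed
  netA <- buildRegionNetwork(V, V, parc, seed = 11, minPerms = 200,
                             maxPerms = 200)
  netB <- buildRegionNetwork(V, V, parc, seed = 11, minPerms = 200,
                             maxPerms = 200)
  expect_identical(networkEdges(netA), networkEdges(netB))
})
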