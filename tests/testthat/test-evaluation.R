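test_that("consensus entries are co-clustering proportions", {
  cm <- consensusMatrix(cbind(c(1, 1, 2), c(1, 1, 2)))
  v <- consensusValues(cm)
  expect_equal(v[1, 2], 1)
  expect_equal(v[1, 3], 0)
  expect_equal(v[2, 3], 0)

  cm2 <- consensusMatrix(cbind(c(1, 1, 2), c(1, 2, 2)))
  v2 <- consensusValues(cm2)
  expect_equal(v2[1, 2], 0.5)
  expect_equal(v2[2, 3], 0.5)
  expect_equal(v2[1, 3], 0)

  single <- consensusValues(consensusMatrix(cbind(c(1, 2, 1, 2))))
  expect_true(all(single %in% c(0, 1)))
})

test_that("consensus matrices match brute-force pair counting", {
  set.seed(91)
  for (case in 1:50) {
    n <- 20
    runs <- sample(1:10, 1)
    lm <- matrix(sample(1:4, n * runs, replace = TRUE), n, runs)
    if (case %% 2 == 0) lm[sample(length(lm), n)] <- NA # pre-completion slices
    keep <- colSums(!is.na(lm)) > 0
    lm <- lm[, keep, drop = FALSE]
    if (!ncol(lm)) next
    expect_equal(
      consensusValues(consensusMatrix(lm)),
      bruteConsensusMatrix(lm),
      ignore_attr = TRUE
    )
  }
})

test_that("the consensus CDF is the ECDF of upper-triangle entries", {
  pm <- new("ConsensusMatrix",
    values = {
      v <- matrix(0.5, 4, 4)
      diag(v) <- 1
      v
    },
    coCount = matrix(1, 4, 4), jointCount = matrix(2, 4, 4), nRuns = 2L, k = 2L
  )
  f <- consensusCDF(pm)
  expect_equal(f(0.49), 0)
  expect_equal(f(0.5), 1)

  twoBlocks <- consensusMatrix(cbind(rep(1:2, each = 2)))
  g <- consensusCDF(twoBlocks)
  expect_equal(g(0), 4 / 6) # 4 of 6 pairs lie between the blocks
  expect_equal(g(1), 1)
})

test_that("CDF areas and their relative changes follow the step integral", {
  stepCDF <- function(values) {
    f <- ecdf(values)
    attr(f, "values") <- sort(values)
    f
  }
  # point mass at 0 -> full area
  expect_equal(unname(deltaAUC(list(`2` = stepCDF(rep(0, 6))))), 1)
  # mass 2/3 at 0 and 1/3 at 1 -> area 2/3
  expect_equal(
    unname(deltaAUC(list(`2` = stepCDF(c(0, 0, 1))))), 2 / 3
  )
  # explicit trapezoid over the step function agrees with the closed form
  set.seed(3)
  vals <- runif(40)
  f <- stepCDF(vals)
  grid <- sort(unique(c(0, vals, 1)))
  trap <- sum(diff(grid) * f(grid[-length(grid)]))
  expect_equal(unname(deltaAUC(list(`2` = f))), trap, tolerance = 1e-12)
  # identical CDFs at consecutive k -> zero relative change
  d <- deltaAUC(list(`2` = f, `3` = f))
  expect_equal(unname(d["3"]), 0)
})

test_that("PAC counts the open ambiguity interval", {
  fromValues <- function(vals) {
    # symmetric 4x4 matrix with the 6 upper-triangle entries given
    v <- diag(4)
    v[upper.tri(v)] <- vals
    v <- v + t(v)
    diag(v) <- 1
    new("ConsensusMatrix",
      values = v, coCount = v, jointCount = matrix(1, 4, 4),
      nRuns = 1L, k = 2L
    )
  }
  expect_equal(pac(fromValues(c(0, 1, 0, 1, 0, 1)), 0.1, 0.9), 0)
  expect_equal(pac(fromValues(rep(0.5, 6)), 0.1, 0.9), 1)
  cmMix <- fromValues(c(0.2, 0.95, 0.5, 1.0, 0.05, 0.5))
  expect_equal(pac(cmMix, 0.1, 0.9), 0.5)
  expect_equal(pac(cmMix, 0.1, 0.9), brutePAC(consensusValues(cmMix), 0.1, 0.9))

  # PAC + CDF tails partition the entries when none sit on a bound
  set.seed(12)
  vals <- runif(6)
  cmR <- fromValues(vals)
  f <- consensusCDF(cmR)
  expect_equal(pac(cmR, 0.25, 0.75) + f(0.25) + (1 - f(0.75)), 1,
    tolerance = 1e-12
  )
})

test_that("the smallest-PAC cluster size is selected", {
  expect_identical(selectK(c(`2` = 0.40, `3` = 0.10, `4` = 0.25)), 3L)
  expect_identical(selectK(c(`2` = 0.10, `3` = 0.10)), 2L)
  expect_identical(selectK(c(`2` = 0.9)), 2L)
  expect_error(selectK(c(`2` = NA_real_)), "undefined")
})

test_that("the default internal suite has thirteen directed indices", {
  fx <- blobFixture(nPer = c(10, 10), p = 4, seed = 3)
  sc <- internalIndices(fx$data, fx$labels)
  expect_identical(nrow(sc), 13L)
  reg <- internalIndexRegistry()
  expect_identical(sc$index, reg$index)
  expect_identical(sc$direction, reg$direction)
  expect_true(all(is.finite(sc$score)))
})

test_that("silhouette behaves on tight blobs and random labels", {
  fx <- simulateMixture(c(15, 15), nFeatures = 5, centers = 50, clusterSd = 0.1, seed = 9)
  sc <- internalIndices(fx$data, fx$labels, "silhouette")
  expect_gt(sc$score, 0.99)
  expect_equal(sc$score, bruteSilhouette(fx$data, fx$labels), tolerance = 1e-10)

  set.seed(8)
  rnd <- sample(fx$labels)
  scr <- internalIndices(fx$data, rnd, "silhouette")
  expect_lt(scr$score, 0.2)
  expect_equal(scr$score, bruteSilhouette(fx$data, rnd), tolerance = 1e-10)
})

test_that("degenerate partitions yield flagged index values, not errors", {
  x <- rbind(a = c(0, 0), b = c(5, 5), c = c(0, 0.01), d = c(5, 5.01))
  # two singleton clusters plus their twins: zero within-diameter -> Dunn Inf
  twoSingletons <- internalIndices(rbind(c(0, 0), c(5, 5), c(10, 0)), c(1, 2, 3))
  expect_true(is.infinite(twoSingletons$score[twoSingletons$index == "dunn"]))

  oneCluster <- internalIndices(x, c(1, 1, 1, 1))
  expect_true(all(is.na(oneCluster$score[oneCluster$index != "compactness"])))
  expect_true(is.finite(oneCluster$score[oneCluster$index == "compactness"]))
})

test_that("external indices are exact on identities and permutations", {
  same <- externalIndices(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(unname(same), c(1, 1, 1))
  flipped <- externalIndices(c(1, 1, 2, 2), c(2, 2, 1, 1))
  expect_equal(unname(flipped["ari"]), 1)
  expect_equal(unname(flipped["accuracy"]), 1)
})

test_that("the ARI matches the permutation-average oracle", {
  expect_equal(
    unname(externalIndices(c(1, 1, 1, 2), c(1, 1, 2, 2))["ari"]),
    bruteARI(c(1L, 1L, 1L, 2L), c(1L, 1L, 2L, 2L))
  )
  set.seed(61)
  for (case in 1:8) {
    n <- sample(5:7, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(
      unname(externalIndices(a, b)["ari"]), bruteARI(a, b),
      tolerance = 1e-10
    )
    # symmetry
    expect_equal(
      unname(externalIndices(a, b)["ari"]),
      unname(externalIndices(b, a)["ari"])
    )
  }
})

test_that("ARI of independent random partitions is centred at zero", {
  set.seed(77)
  aris <- replicate(100, {
    a <- sample(1:4, 200, replace = TRUE)
    b <- sample(1:4, 200, replace = TRUE)
    unname(externalIndices(a, b)["ari"])
  })
  expect_lt(abs(mean(aris)), 0.05)
})
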