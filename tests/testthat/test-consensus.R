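test_that("relabelling maximises contingency overlap", {
  expect_identical(relabelPartition(c(2, 2, 1, 1), c(1, 1, 2, 2)), c(1L, 1L, 2L, 2L))
  expect_identical(relabelPartition(c(1, 2, 1, 2), c(1, 2, 1, 2)), c(1L, 2L, 1L, 2L))
  # k1 > k2: the extra cluster maps onto a padded (unused) ID
  out <- relabelPartition(c(1, 1, 2, 3), c(1, 1, 2, 2))
  expect_identical(out[1:3], c(1L, 1L, 2L))
  expect_identical(out[4], 3L) # sample 4 stays in its own cluster
  expect_error(relabelPartition(1:3, 1:4), "length")
})

test_that("relabelling matches the exhaustive-permutation oracle", {
  set.seed(31)
  for (case in 1:20) {
    n <- sample(5:9, 1)
    labels <- sample(1:3, n, replace = TRUE)
    reference <- sample(1:3, n, replace = TRUE)
    out <- relabelPartition(labels, reference)
    # memberships unchanged
    expect_identical(outer(out, out, "=="), outer(labels, labels, "=="))
    # achieved overlap equals the brute-force optimum
    expect_equal(sum(out == reference), bruteRelabelOverlap(labels, reference))
  }
})

test_that("majority voting aligns runs before counting votes", {
  unanimity <- cbind(c(1, 1, 2, 2), c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_identical(clusterLabels(majorityVote(unanimity, 2)), c(1L, 1L, 2L, 2L))

  permuted <- cbind(c(1, 1, 2, 2), c(2, 2, 1, 1), c(2, 2, 1, 1))
  expect_identical(clusterLabels(majorityVote(permuted, 2)), c(1L, 1L, 2L, 2L))

  # one dissenting run on sample 2: votes after alignment are (1, 1, 2)
  dissent <- cbind(c(1, 1, 2, 2), c(1, 1, 2, 2), c(1, 2, 2, 2))
  expect_identical(clusterLabels(majorityVote(dissent, 2)), c(1L, 1L, 2L, 2L))
})

test_that("k-modes recovers grouped label vectors", {
  two <- rbind(
    c(1, 1, 1), c(1, 1, 1), c(1, 1, 1),
    c(2, 2, 2), c(2, 2, 2), c(2, 2, 2)
  )
  sol <- kmodesConsensus(two, 2, seed = 5)
  expect_identical(clusterLabels(sol), rep(c(1L, 2L), each = 3))
  expect_false(sol@degenerate)

  same <- matrix(1L, 5, 3)
  expect_warning(deg <- kmodesConsensus(same, 2, seed = 1), "distinct")
  expect_true(deg@degenerate)
})

test_that("k-modes attains the brute-force simple-matching optimum", {
  # two groups of label vectors with one flipped position each
  lm <- rbind(
    c(1, 1, 1, 1), c(1, 2, 1, 1), c(1, 1, 2, 1),
    c(2, 2, 2, 2), c(2, 1, 2, 2), c(2, 2, 1, 2)
  )
  # oracle: exhaustive 2-partitions, cost = matching distance to group modes
  bestCost <- Inf
  bestPart <- NULL
  for (mask in 1:(2^6 - 2)) {
    part <- as.integer(intToBits(mask))[1:6] + 1L
    if (length(unique(part)) < 2) next
    cost <- 0
    for (g in 1:2) {
      rows <- lm[part == g, , drop = FALSE]
      if (!nrow(rows)) next
      mode <- apply(rows, 2, function(v) which.max(tabulate(v)))
      cost <- cost + sum(rows != matrix(mode, nrow(rows), 4, byrow = TRUE))
    }
    if (cost < bestCost) {
      bestCost <- cost
      bestPart <- part
    }
  }
  sol <- kmodesConsensus(lm, 2, seed = 3)
  expect_equal(unname(externalIndices(clusterLabels(sol), bestPart)["ari"]), 1)
})

test_that("CSPA cuts the co-association dendrogram", {
  blockCM <- function(blocks) {
    n <- sum(blocks)
    v <- matrix(0, n, n)
    start <- 1
    for (b in blocks) {
      idx <- start:(start + b - 1)
      v[idx, idx] <- 1
      start <- start + b
    }
    new("ConsensusMatrix",
      values = v, coCount = v, jointCount = matrix(1, n, n),
      nRuns = 1L, k = length(blocks)
    )
  }
  lmDummy <- cbind(rep(1:2, each = 3))
  sol <- cspa(lmDummy, 2, cm = blockCM(c(3, 3)))
  expect_identical(clusterLabels(sol), rep(c(1L, 2L), each = 3))
  expect_false(sol@degenerate)

  ones <- blockCM(6)
  deg <- cspa(lmDummy, 2, cm = ones)
  expect_true(deg@degenerate)

  # 3 noisy blocks: within >= 0.9, between <= 0.1
  set.seed(17)
  v <- matrix(runif(15^2, 0, 0.1), 15, 15)
  for (b in 0:2) v[b * 5 + 1:5, b * 5 + 1:5] <- runif(25, 0.9, 1)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  cm3 <- new("ConsensusMatrix",
    values = v, coCount = v, jointCount = matrix(1, 15, 15),
    nRuns = 1L, k = 3L
  )
  sol3 <- cspa(cbind(rep(1:3, each = 5)), 3, cm = cm3)
  expect_equal(unname(externalIndices(clusterLabels(sol3), rep(1:3, each = 5))["ari"]), 1)
})

test_that("LCE refines associations and recovers known structure", {
  identical9 <- matrix(rep(c(1, 1, 1, 2, 2, 2, 3, 3, 3), 5), ncol = 5)
  for (dcv in c(0, 0.5, 1)) {
    sol <- lce(identical9, 3, dc = dcv)
    expect_equal(
      unname(externalIndices(clusterLabels(sol), rep(1:3, each = 3))["ari"]), 1
    )
  }
  expect_error(lce(identical9, 3, dc = 1.5), "dc")

  # dc = 0 reduces to clustering the binary membership rows
  set.seed(23)
  lm <- cbind(
    c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 2, 2, 1), c(2, 2, 2, 1, 1, 1)
  )
  sol0 <- lce(lm, 2, dc = 0)
  M <- do.call(cbind, lapply(1:3, function(j) {
    outer(lm[, j], sort(unique(lm[, j])), "==") * 1L
  }))
  ref <- cutree(hclust(dist(M), method = "average"), k = 2)
  expect_equal(unname(externalIndices(clusterLabels(sol0), ref)["ari"]), 1)

  # noisy runs on a separated 2-blob fixture
  fx <- blobFixture(nPer = c(12, 12), p = 4, seed = 41)
  lmBlob <- smallLabelMatrix(fx, k = 2, reps = 5, seed = 6)
  solB <- lce(lmBlob, 2)
  expect_equal(unname(externalIndices(clusterLabels(solB), fx$labels)["ari"]), 1)
})

test_that("all methods are invariant to run relabelling and sample order", {
  fx <- blobFixture(nPer = c(10, 10, 10), p = 4, seed = 13)
  lm <- smallLabelMatrix(fx, k = 3, reps = 3, seed = 19)
  runOne <- function(method, m) {
    clusterLabels(runConsensus(method, m, k = 3, seed = 77))
  }
  set.seed(55)
  for (method in consensusMethods()) {
    base <- runOne(method, lm)
    # permute cluster IDs within every run
    shuffled <- lm
    for (j in seq_len(ncol(lm))) {
      perm <- sample(3)
      shuffled[, j] <- perm[lm[, j]]
    }
    attr(shuffled, "k") <- 3L
    expect_equal(
      unname(externalIndices(runOne(method, shuffled), base)["ari"]), 1,
      info = paste(method, "label permutation")
    )
    # permute sample order
    ord <- sample(nrow(lm))
    reordered <- lm[ord, , drop = FALSE]
    attr(reordered, "k") <- 3L
    expect_equal(
      unname(externalIndices(runOne(method, reordered), base[ord])["ari"]), 1,
      info = paste(method, "sample order")
    )
    # identical columns reproduce the common partition
    mono <- matrix(rep(base, 4), ncol = 4)
    expect_equal(
      unname(externalIndices(runOne(method, mono), base)["ari"]), 1,
      info = paste(method, "unanimity")
    )
  }
})
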