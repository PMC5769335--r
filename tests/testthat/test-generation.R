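test_that("the default registry holds the ten advertised algorithms", {
  reg <- builtinAlgorithms()
  expect_length(reg, 10)
  expect_setequal(
    names(reg),
    c(
      "kmeans", "pam", "hc_average", "hc_complete", "hc_ward", "diana",
      "spectral", "gmm", "cmeans", "som"
    )
  )
  expect_identical(reg$kmeans$needs, "raw_data")
  expect_identical(reg$pam$needs, "distance_matrix")
  expect_error(addAlgorithm(reg, algorithmSpec("kmeans", "raw_data", function(i, k, s) 1L)),
    "already registered"
  )
})

test_that("every registry entry obeys the labelling contract on easy data", {
  fx <- simulateMixture(c(6, 6), nFeatures = 2, centers = 12, seed = 2)
  dists <- lapply(
    setNames(nm = supportedMetrics()),
    function(m) pairwiseDistance(fx$data, m)
  )
  for (spec in builtinAlgorithms()) {
    input <- if (spec$needs == "raw_data") fx$data else dists[[spec$metric]]
    lab <- spec$fun(input, 2, 99)
    expect_length(lab, 12)
    expect_true(all(lab %in% 1:2), info = spec$name)
  }
})

test_that("subsampling draws reproducible 80% index sets", {
  subs <- subsampleIndices(100, 0.8, reps = 5, seed = 3)
  expect_length(subs, 5)
  expect_true(all(lengths(subs) == 80))
  expect_gt(length(unique(vapply(subs, paste, character(1), collapse = ","))), 1)
  expect_identical(subs, subsampleIndices(100, 0.8, reps = 5, seed = 3))

  full <- subsampleIndices(10, 1.0, reps = 3, seed = 1)
  expect_true(all(vapply(full, identical, logical(1), 1:10)))

  expect_error(subsampleIndices(3, 0.5, reps = 1, seed = 1), "too small")
})

test_that("the clustering array respects subsample provenance", {
  fx <- blobFixture(nPer = c(25, 25), p = 4, seed = 5)
  ce <- suppressMessages(generateArray(fx$data,
    kValues = c(2, 3),
    algorithms = builtinAlgorithms(c("kmeans", "hc_average")),
    reps = 3, fraction = 0.8, seed = 21
  ))
  arr <- clusterLabels(ce)
  expect_identical(dim(arr), c(50L, 3L, 2L, 2L))
  for (r in 1:3) {
    for (a in 1:2) {
      for (ki in 1:2) {
        slice <- arr[, r, a, ki]
        expect_identical(unname(which(!is.na(slice))), ce@subsamples[[r]])
        expect_identical(sum(is.na(slice)), 10L) # 50 - round(0.8 * 50)
      }
    }
  }
  # determinism
  ce2 <- suppressMessages(generateArray(fx$data,
    kValues = c(2, 3),
    algorithms = builtinAlgorithms(c("kmeans", "hc_average")),
    reps = 3, fraction = 0.8, seed = 21
  ))
  expect_identical(clusterLabels(ce), clusterLabels(ce2))
})

test_that("separable data is partitioned identically across full-data reps", {
  fx <- blobFixture(nPer = c(10, 10), p = 3, seed = 8)
  ce <- generateArray(fx$data,
    kValues = 2,
    algorithms = builtinAlgorithms("kmeans"), reps = 2, fraction = 1, seed = 4
  )
  s1 <- clusterLabels(ce)[, 1, 1, 1]
  s2 <- clusterLabels(ce)[, 2, 1, 1]
  expect_equal(unname(externalIndices(s1, s2)["ari"]), 1)
  expect_equal(unname(externalIndices(s1, fx$labels)["ari"]), 1)
})

test_that("knn completion uses majority voting with smallest-label ties", {
  # geometry: the missing sample d is closest to a, b, c in that order
  x <- rbind(
    a = c(0, 0), b = c(0.15, 0.05), c = c(0, 0.2), d = c(0.05, 0.05),
    e = c(10, 10), f = c(10.2, 10)
  )
  makeEnsemble <- function(labs) {
    labels <- array(NA_integer_, c(6, 1, 1, 1), dimnames = list(rownames(x), "R1", "alg", "2"))
    labels[c(1, 2, 3, 5, 6), 1, 1, 1] <- labs
    new("ClusterEnsemble",
      labels = labels, kValues = 2L,
      subsamples = list(c(1L, 2L, 3L, 5L, 6L)), completed = FALSE, data = x,
      failures = character(0)
    )
  }
  # neighbours labelled (1, 1, 2) with knnK = 3 -> majority label 1
  done <- completeByKNN(makeEnsemble(c(1L, 1L, 2L, 2L, 2L)), knnK = 3)
  expect_identical(unname(clusterLabels(done)["d", 1, 1, 1]), 1L)

  # neighbours labelled (1, 2) with knnK = 2 -> tie, smallest label wins
  tie <- completeByKNN(makeEnsemble(c(1L, 2L, 2L, 2L, 2L)), knnK = 2)
  expect_identical(unname(clusterLabels(tie)["d", 1, 1, 1]), 1L)

  # idempotence and the full-fraction identity
  expect_identical(clusterLabels(completeByKNN(done, 3)), clusterLabels(done))
  fx <- blobFixture(nPer = c(8, 8), p = 3, seed = 12)
  full <- generateArray(fx$data,
    kValues = 2, algorithms = builtinAlgorithms("pam"),
    reps = 2, fraction = 1, seed = 2
  )
  expect_identical(clusterLabels(completeByKNN(full)), clusterLabels(full))
})

test_that("a point on a cluster centroid is completed into that cluster", {
  fx <- simulateMixture(c(15, 15), nFeatures = 3, centers = 10, seed = 30)
  centre1 <- colMeans(fx$data[fx$labels == 1, ])
  x <- rbind(fx$data, probe = centre1)
  ce <- suppressMessages(generateArray(x,
    kValues = 2,
    algorithms = builtinAlgorithms(c("kmeans", "hc_average")),
    reps = 4, fraction = 0.8, seed = 9
  ))
  done <- completeByKNN(ce)
  probe <- clusterLabels(done)["probe", , , 1]
  cluster1 <- clusterLabels(done)[which(fx$labels == 1)[1], , , 1]
  expect_identical(unname(probe), unname(cluster1))
})

test_that("an all-missing slice errors unless explicitly skipped", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  labels <- array(NA_integer_, c(10, 1, 1, 1),
    dimnames = list(rownames(x), "R1", "broken", "2")
  )
  ce <- new("ClusterEnsemble",
    labels = labels, kValues = 2L,
    subsamples = list(1:10), completed = FALSE, data = x, failures = "broken"
  )
  expect_error(completeByKNN(ce), "broken")
  skipped <- completeByKNN(ce, skipEmpty = TRUE)
  expect_false(isCompleted(skipped))
})
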