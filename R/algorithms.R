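## Base clustering algorithm registry. Each entry is a self-contained spec:
## what input it consumes (raw data or a distance matrix), which distance
## metric it uses, and a callable (input, k, seed) -> integer labels in 1..k.
## Users can extend the registry with their own algorithm or distance.

#' Define a base clustering algorithm
#'
#' @param name unique algorithm name.
#' @param needs `"raw_data"` or `"distance_matrix"`.
#' @param fun function `(input, k, seed)` returning one integer label in
#'   `1..k` per input sample. `input` is the prepared data matrix
#'   (`needs = "raw_data"`) or the pairwise distance matrix.
#' @param metric the distance metric the algorithm consumes (for
#'   `distance_matrix` algorithms) or is naturally compatible with.
#' @return an `AlgorithmSpec` (a classed list).
#' @export
algorithmSpec <- function(name, needs = c("raw_data", "distance_matrix"),
                          fun, metric = "euclidean") {
  needs <- match.arg(needs)
  stopIfNot(is.character(name) && length(name) == 1 && nzchar(name), "name must be a string")
  stopIfNot(is.function(fun), "fun must be a function(input, k, seed)")
  stopIfNot(metric %in% supportedMetrics(), "unknown metric '", metric, "'")
  structure(list(name = name, needs = needs, fun = fun, metric = metric),
    class = "AlgorithmSpec"
  )
}

#' @export
print.AlgorithmSpec <- function(x, ...) {
  cat(sprintf("AlgorithmSpec '%s' (%s, %s)\n", x$name, x$needs, x$metric))
  invisible(x)
}

#' Add an algorithm to a registry
#'
#' @param registry named list of [algorithmSpec()] entries.
#' @param spec the spec to add.
#' @return the extended registry.
#' @export
addAlgorithm <- function(registry, spec) {
  stopIfNot(inherits(spec, "AlgorithmSpec"), "spec must come from algorithmSpec()")
  stopIfNot(
    !(spec$name %in% names(registry)),
    "algorithm '", spec$name, "' is already registered"
  )
  registry[[spec$name]] <- spec
  registry
}

hcSpec <- function(name, linkage, metric = "euclidean") {
  algorithmSpec(name, "distance_matrix", metric = metric, fun = function(input, k, seed) {
    cutree(hclust(as.dist(input), method = linkage), k = k)
  })
}

#' The default registry of ten diverse base algorithms
#'
#' Partitional (k-means, PAM, fuzzy c-means hardened by largest membership),
#' hierarchical agglomerative (average, complete, Ward linkage), divisive
#' (DIANA), model-based (Gaussian mixture), graph-based (spectral) and
#' prototype-based (self-organising map followed by partitioning of the
#' codebook). Implementations come from the standard clustering stack
#' (stats, cluster, e1071, mclust, kernlab, class); every entry obeys the
#' `(input, k, seed) -> labels in 1..k` contract.
#'
#' @param names optional character vector selecting a subset by name.
#' @return named list of `AlgorithmSpec` entries.
#' @export
#' @examples
#' names(builtinAlgorithms())
builtinAlgorithms <- function(names = NULL) {
  reg <- list()
  reg <- addAlgorithm(reg, algorithmSpec("kmeans", "raw_data", function(input, k, seed) {
    withSeed(seed, kmeans(input, centers = k, nstart = 10, iter.max = 50)$cluster)
  }))
  reg <- addAlgorithm(reg, algorithmSpec("pam", "distance_matrix", function(input, k, seed) {
    cluster::pam(as.dist(input), k = k, cluster.only = TRUE)
  }))
  reg <- addAlgorithm(reg, hcSpec("hc_average", "average"))
  reg <- addAlgorithm(reg, hcSpec("hc_complete", "complete"))
  reg <- addAlgorithm(reg, hcSpec("hc_ward", "ward.D2"))
  reg <- addAlgorithm(reg, algorithmSpec("diana", "distance_matrix", function(input, k, seed) {
    cutree(as.hclust(cluster::diana(as.dist(input), diss = TRUE)), k = k)
  }))
  reg <- addAlgorithm(reg, algorithmSpec("spectral", "raw_data", function(input, k, seed) {
    withSeed(seed, as.integer(kernlab::specc(as.matrix(input), centers = k)))
  }))
  reg <- addAlgorithm(reg, algorithmSpec("gmm", "raw_data", function(input, k, seed) {
    fit <- withSeed(seed, Mclust(input, G = k, verbose = FALSE))
    stopIfNot(!is.null(fit), "Gaussian mixture fit failed")
    as.integer(fit$classification)
  }))
  reg <- addAlgorithm(reg, algorithmSpec("cmeans", "raw_data", function(input, k, seed) {
    fit <- withSeed(seed, e1071::cmeans(input, centers = k, iter.max = 100))
    as.integer(apply(fit$membership, 1, which.max))
  }))
  reg <- addAlgorithm(reg, algorithmSpec("som", "raw_data", function(input, k, seed) {
    withSeed(seed, {
      gridDim <- max(2L, ceiling(sqrt(sqrt(nrow(input)) * 2)))
      som <- class::batchSOM(input, class::somgrid(gridDim, gridDim, "rectangular"),
        radii = c(2, 1, 1, 0)
      )
      unit <- apply(input, 1, function(p) {
        which.min(colSums((t(som$codes) - p)^2))
      })
      codeCl <- kmeans(som$codes, centers = k, nstart = 10)$cluster
      as.integer(codeCl[unit])
    })
  }))
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(reg))
    stopIfNot(!length(missing), "unknown algorithm(s): ", paste(missing, collapse = ", "))
    reg <- reg[names]
  }
  reg
}
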