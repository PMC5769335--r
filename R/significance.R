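## Monte-Carlo significance test of a 2-way split against a single
## multivariate Gaussian null (SigClust-style): compare the observed
## 2-means cluster index with its distribution under a Gaussian with the
## (noise-floored) sample covariance eigenvalues.

#' Cluster index of a two-way split
#'
#' `CI = within-cluster sum of squares / total sum of squares`, computed on
#' the raw coordinates. Values near 0 indicate a tight, well-separated
#' split; CI is invariant to rotation and translation of the data.
#'
#' @param x numeric matrix (samples x features).
#' @param labels2 partition into exactly two non-empty clusters.
#' @return CI in `[0, 1]`.
#' @export
#' @examples
#' x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
#' clusterIndex(x, c(1, 1, 2, 2))
clusterIndex <- function(x, labels2) {
  x <- as.matrix(x)
  labels2 <- denseLabels(labels2)
  stopIfNot(length(labels2) == nrow(x), "one label per sample required")
  stopIfNot(max(labels2) == 2, "exactly two non-empty clusters required")
  grand <- colMeans(x)
  tss <- sum(sweep(x, 2, grand)^2)
  stopIfNot(tss > 0, "total sum of squares is zero (all points identical)")
  wss <- sum(vapply(1:2, function(c) {
    xc <- x[labels2 == c, , drop = FALSE]
    sum(sweep(xc, 2, colMeans(xc))^2)
  }, numeric(1)))
  wss / tss
}

#' Eigenvalues of the Gaussian null covariance
#'
#' The null is a mean-zero Gaussian whose diagonal covariance holds the
#' sample-covariance eigenvalues floored at a background noise variance:
#' `sigma2 = (MAD of all column-centred data values / 0.6745)^2`, the
#' normal-consistent variance of the measurement noise. Flooring
#' (`max(lambda_j, sigma2)`) prevents the null from collapsing along
#' low-variance directions.
#'
#' @param x numeric matrix (samples x features).
#' @return numeric vector of floored eigenvalues, one per feature.
#' @export
estimateNullEigenvalues <- function(x) {
  x <- as.matrix(x)
  stopIfNot(nrow(x) > 1, "need more than one sample")
  ev <- eigen(cov(x), symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0 # numerical guard
  centred <- as.vector(sweep(x, 2, colMeans(x)))
  sigma2 <- (mad(centred, constant = 1) / 0.6745)^2
  pmax(ev, sigma2)
}

bestTwoMeans <- function(x, restarts, seed) {
  # CI minimisation over 2-way splits = within-SS minimisation, which is
  # exactly the 2-means objective
  fit <- withSeed(seed, kmeans(x, centers = 2, nstart = restarts, iter.max = 50))
  denseLabels(fit$cluster)
}

#' Monte-Carlo significance test of a two-cluster split
#'
#' Tests whether the observed 2-way split is tighter than expected under a
#' single Gaussian. The observed cluster index comes from `labels2`, or
#' from the best 2-means split (multiple seeded restarts) when `labels2` is
#' absent. `nSim` null datasets of the same shape are simulated from a
#' mean-zero Gaussian with diagonal covariance [estimateNullEigenvalues()],
#' each reduced to its minimal 2-means cluster index, and the p-value is
#' the add-one estimator `(1 + #{null CI <= observed CI}) / (1 + nSim)`.
#'
#' @param x numeric matrix (samples x features).
#' @param labels2 optional two-cluster partition to test.
#' @param nSim number of null simulations, default 1000.
#' @param seed integer seed.
#' @param restarts 2-means restarts per CI minimisation, default 20.
#' @return list of class `sigclust` with `observed_ci`, `null_cis`,
#'   `p_value`, `n_sim`, `seed`.
#' @export
sigclust <- function(x, labels2 = NULL, nSim = 1000, seed = 1, restarts = 20) {
  x <- as.matrix(x)
  stopIfNot(nSim >= 1, "nSim must be >= 1")
  if (is.null(labels2)) labels2 <- bestTwoMeans(x, restarts, deriveSeed(seed, "observed"))
  observed <- clusterIndex(x, labels2)
  lambda <- estimateNullEigenvalues(x)
  n <- nrow(x)
  p <- ncol(x)
  sdVec <- sqrt(lambda)
  nullCIs <- vapply(seq_len(nSim), function(s) {
    simSeed <- deriveSeed(seed, "null", s)
    sim <- withSeed(simSeed, matrix(rnorm(n * p), n, p) %*% diag(sdVec, p))
    clusterIndex(sim, bestTwoMeans(sim, restarts, deriveSeed(simSeed, "split")))
  }, numeric(1))
  structure(
    list(
      observed_ci = observed,
      null_cis = nullCIs,
      p_value = (1 + sum(nullCIs <= observed)) / (1 + nSim),
      n_sim = as.integer(nSim),
      seed = as.integer(seed)
    ),
    class = "sigclust"
  )
}

#' @export
print.sigclust <- function(x, ...) {
  cat(sprintf(
    "sigclust: observed CI %.4f, p = %.4g (%d null simulations)\n",
    x$observed_ci, x$p_value, x$n_sim
  ))
  invisible(x)
}

#' Significance of the clusters of a final partition
#'
#' Top-down driver: tests the best 2-means split of the full data against
#' the Gaussian null, then (for partitions with more than two clusters)
#' each individual cluster large enough to split. Raw p-values are reported
#' without multiplicity correction.
#'
#' @param x numeric matrix (samples x features).
#' @param labels final partition.
#' @param nSim null simulations per test.
#' @param seed integer seed.
#' @param minSize smallest cluster size worth splitting, default 10.
#' @return data frame (comparison, observed_ci, p_value, n_sim).
#' @export
significanceDriver <- function(x, labels, nSim = 100, seed = 1, minSize = 10) {
  labels <- denseLabels(labels)
  out <- list()
  top <- sigclust(x, nSim = nSim, seed = deriveSeed(seed, "top"))
  out[[1]] <- data.frame(
    comparison = "all_samples_2_vs_1",
    observed_ci = top$observed_ci, p_value = top$p_value, n_sim = nSim,
    stringsAsFactors = FALSE
  )
  if (max(labels) > 2) {
    for (c in seq_len(max(labels))) {
      idx <- which(labels == c)
      if (length(idx) < minSize) next
      sub <- x[idx, , drop = FALSE]
      res <- tryCatch(
        sigclust(sub, nSim = nSim, seed = deriveSeed(seed, "cluster", c)),
        error = function(e) NULL
      )
      if (is.null(res)) next
      out[[length(out) + 1]] <- data.frame(
        comparison = sprintf("within_cluster_%d_2_vs_1", c),
        observed_ci = res$observed_ci, p_value = res$p_value, n_sim = nSim,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
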