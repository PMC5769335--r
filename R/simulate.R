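## Synthetic data generators: Gaussian-mixture blobs with known ground
## truth and single-Gaussian null datasets. These define the test-bed
## conditions for every property test and the calibration runs.

#' Centres on a scaled simplex
#'
#' Places `k` cluster centres in `p` dimensions, pairwise `separation`
#' apart (vertices of a regular simplex embedded in the first `k - 1`
#' coordinates, scaled so every pairwise centre distance equals
#' `separation`).
#'
#' @param k number of centres.
#' @param p number of dimensions (`p >= k - 1`).
#' @param separation pairwise centre distance.
#' @return `k x p` matrix of centres.
#' @export
simplexCenters <- function(k, p, separation) {
  stopIfNot(p >= k - 1, "need at least k - 1 dimensions for k equidistant centres")
  centers <- matrix(0, k, p)
  if (k == 1) return(centers)
  # regular simplex: centred identity vertices (pairwise distance sqrt(2))
  # expressed in an orthonormal basis of their (k-1)-dim span, then rescaled
  v <- diag(k) - 1 / k
  basis <- qr.Q(qr(t(v)))[, seq_len(k - 1), drop = FALSE]
  coords <- v %*% basis
  coords <- coords * separation / sqrt(2)
  centers[, seq_len(k - 1)] <- coords
  centers
}

#' Simulate a spherical Gaussian mixture with known labels
#'
#' Each cluster is a spherical Gaussian of standard deviation `clusterSd`
#' around its centre; optional pure-noise features are standard normal for
#' every sample. Labels follow generation order.
#'
#' @param nPerCluster integer vector of cluster sizes.
#' @param nFeatures number of informative features.
#' @param centers `k x nFeatures` matrix of centres, or a single number
#'   taken as the pairwise separation of simplex centres.
#' @param clusterSd within-cluster standard deviation, default 1.
#' @param noiseFeatures extra standard-normal noise features, default 0.
#' @param seed integer seed.
#' @return list with `data` (matrix with sample/feature names) and
#'   `labels` (integer ground truth).
#' @export
#' @examples
#' fx <- simulateMixture(c(20, 20, 20), nFeatures = 5, centers = 10, seed = 1)
#' table(fx$labels)
simulateMixture <- function(nPerCluster, nFeatures, centers,
                            clusterSd = 1, noiseFeatures = 0, seed = 1) {
  k <- length(nPerCluster)
  stopIfNot(k >= 1 && all(nPerCluster >= 1), "cluster sizes must be positive")
  stopIfNot(clusterSd > 0, "clusterSd must be positive")
  if (is.matrix(centers)) {
    stopIfNot(
      nrow(centers) == k && ncol(centers) == nFeatures,
      "centers must be k x nFeatures"
    )
  } else {
    stopIfNot(length(centers) == 1 && centers >= 0, "separation must be a nonnegative scalar")
    centers <- simplexCenters(k, nFeatures, centers)
  }
  n <- sum(nPerCluster)
  labels <- rep(seq_len(k), nPerCluster)
  x <- withSeed(seed, {
    core <- centers[labels, , drop = FALSE] +
      matrix(rnorm(n * nFeatures, sd = clusterSd), n, nFeatures)
    if (noiseFeatures > 0) {
      cbind(core, matrix(rnorm(n * noiseFeatures), n, noiseFeatures))
    } else {
      core
    }
  })
  rownames(x) <- paste0("S", seq_len(n))
  colnames(x) <- paste0("F", seq_len(ncol(x)))
  list(data = x, labels = as.integer(labels))
}

#' Simulate a single-Gaussian null dataset
#'
#' @param n number of samples.
#' @param p number of features.
#' @param covariance `"isotropic"` (identity) or a numeric vector of
#'   diagonal variances of length `p`.
#' @param seed integer seed.
#' @return numeric matrix with sample/feature names.
#' @export
simulateNull <- function(n, p, covariance = "isotropic", seed = 1) {
  vars <- if (identical(covariance, "isotropic")) {
    rep(1, p)
  } else {
    stopIfNot(
      is.numeric(covariance) && length(covariance) == p && all(covariance > 0),
      "covariance must be 'isotropic' or p positive variances"
    )
    covariance
  }
  x <- withSeed(seed, matrix(rnorm(n * p), n, p) %*% diag(sqrt(vars), p))
  rownames(x) <- paste0("S", seq_len(n))
  colnames(x) <- paste0("F", seq_len(p))
  x
}
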