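## Diverse cluster generation: every (algorithm, k) pair is run on repeated
## 80% observation subsamples; unsampled assignments are later completed by
## k-nearest-neighbour majority voting.

#' Draw reproducible observation subsamples
#'
#' Each repetition draws `round(fraction * n)` sample indices without
#' replacement. Draws are reproducible from the seed and (for
#' `fraction < 1`) differ across repetitions with overwhelming probability.
#'
#' @param n number of samples.
#' @param fraction subsample fraction in `(0, 1]`, default 0.8.
#' @param reps number of repetitions.
#' @param seed integer seed.
#' @return list of `reps` sorted integer index vectors.
#' @export
#' @examples
#' lengths(subsampleIndices(100, 0.8, reps = 3, seed = 1))
subsampleIndices <- function(n, fraction = 0.8, reps = 10, seed = 1) {
  stopIfNot(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  stopIfNot(reps >= 1, "reps must be >= 1")
  size <- round(fraction * n)
  stopIfNot(size >= 3, "subsample size ", size, " is too small (< 3)")
  withSeed(seed, lapply(seq_len(reps), function(r) sort(sample.int(n, size))))
}

#' Generate the diverse clustering array
#'
#' Runs every configured algorithm at every cluster size on each
#' repetition's subsample, storing labels in a 4-d array indexed
#' (sample, repetition, algorithm, k). Samples outside a repetition's
#' subsample are `NA`. Per-run seeds are derived deterministically from the
#' global seed and the run coordinates ([deriveSeed()]), so each run is an
#' independent yet reproducible "expert". A failing algorithm run is logged
#' and leaves its slice missing rather than aborting the ensemble.
#'
#' @param x prepared numeric matrix (samples in rows).
#' @param kValues integer vector of cluster sizes, each `>= 2` and smaller
#'   than the subsample size.
#' @param algorithms registry from [builtinAlgorithms()] (possibly extended
#'   or subset).
#' @param reps number of subsample repetitions, default 10.
#' @param fraction observation fraction per subsample, default 0.8.
#' @param seed integer seed.
#' @return a [ClusterEnsemble-class] with missing cells for unsampled cases.
#' @export
generateArray <- function(x, kValues, algorithms = builtinAlgorithms(),
                          reps = 10, fraction = 0.8, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  kValues <- as.integer(sort(unique(kValues)))
  stopIfNot(all(kValues >= 2), "all k values must be >= 2")
  stopIfNot(length(algorithms) >= 1, "need at least one algorithm")
  subs <- subsampleIndices(n, fraction, reps, seed)
  size <- length(subs[[1]])
  stopIfNot(
    all(kValues < size),
    "every k must be smaller than the subsample size (", size, ")"
  )
  algNames <- names(algorithms)
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(n))

  # distance matrices are metric-dependent but subsample-independent:
  # compute once per metric on the full data, subset per repetition
  metricsNeeded <- unique(vapply(
    Filter(function(a) a$needs == "distance_matrix", algorithms),
    `[[`, character(1), "metric"
  ))
  distFull <- lapply(metricsNeeded, function(m) pairwiseDistance(x, m))
  names(distFull) <- metricsNeeded

  labels <- array(NA_integer_, dim = c(n, reps, length(algorithms), length(kValues)),
    dimnames = list(
      rownames(x), paste0("R", seq_len(reps)), algNames, as.character(kValues)
    )
  )
  failures <- character(0)
  for (r in seq_len(reps)) {
    idx <- subs[[r]]
    for (a in seq_along(algorithms)) {
      spec <- algorithms[[a]]
      input <- if (spec$needs == "raw_data") {
        x[idx, , drop = FALSE]
      } else {
        distFull[[spec$metric]][idx, idx, drop = FALSE]
      }
      for (ki in seq_along(kValues)) {
        k <- kValues[ki]
        runSeed <- deriveSeed(seed, r, spec$name, k)
        lab <- tryCatch(as.integer(spec$fun(input, k, runSeed)), error = function(e) e)
        if (inherits(lab, "error")) {
          failures <- c(failures, sprintf(
            "%s rep %d k %d: %s", spec$name, r, k, conditionMessage(lab)
          ))
          next
        }
        if (length(lab) != length(idx) || anyNA(lab) || any(lab < 1L | lab > k)) {
          failures <- c(failures, sprintf(
            "%s rep %d k %d: invalid label vector returned", spec$name, r, k
          ))
          next
        }
        labels[idx, r, a, ki] <- lab
      }
    }
  }
  nRuns <- reps * length(algorithms) * length(kValues)
  stopIfNot(length(failures) < nRuns, "all clustering runs failed")
  if (length(failures)) {
    message(length(failures), " of ", nRuns, " clustering runs failed and were left missing")
  }
  new("ClusterEnsemble",
    labels = labels, kValues = kValues, subsamples = subs,
    completed = FALSE, data = x, failures = failures
  )
}

#' Complete missing assignments by k-nearest-neighbour majority voting
#'
#' For every missing (sample, repetition, algorithm, k) cell, the sample is
#' assigned the majority label among its `knnK` nearest neighbours
#' (Euclidean distance in the prepared feature space) that are non-missing
#' in the same slice; ties go to the smallest label. Completion is
#' idempotent, and for a subsample fraction of 1 it is the identity.
#'
#' @param ensemble a [ClusterEnsemble-class].
#' @param knnK number of neighbours, default 5.
#' @param skipEmpty if `TRUE`, slices with no non-missing sample (failed
#'   algorithm runs) are left missing instead of raising an error; the
#'   pipeline uses this to drop failed runs downstream.
#' @return the completed [ClusterEnsemble-class].
#' @export
completeByKNN <- function(ensemble, knnK = 5, skipEmpty = FALSE) {
  stopIfNot(knnK >= 1, "knnK must be >= 1")
  labels <- ensemble@labels
  d <- dim(labels)
  distE <- as.matrix(dist(ensemble@data))
  anyEmpty <- FALSE
  for (ki in seq_len(d[4])) {
    for (a in seq_len(d[3])) {
      for (r in seq_len(d[2])) {
        slice <- labels[, r, a, ki]
        miss <- which(is.na(slice))
        if (!length(miss)) next
        present <- which(!is.na(slice))
        if (!length(present)) {
          if (skipEmpty) {
            anyEmpty <- TRUE
            next
          }
          stop(sprintf(
            "slice (rep %s, algorithm %s, k %s) has no assigned samples",
            dimnames(labels)[[2]][r], dimnames(labels)[[3]][a],
            dimnames(labels)[[4]][ki]
          ), call. = FALSE)
        }
        kk <- min(knnK, length(present))
        for (i in miss) {
          nn <- present[order(distE[i, present])[seq_len(kk)]]
          labels[i, r, a, ki] <- modalLabel(slice[nn])
        }
      }
    }
  }
  initialize(ensemble, labels = labels, completed = !anyEmpty)
}

#' Extract one k-slice of a completed ensemble as a label matrix
#'
#' Columns are runs (repetition x algorithm); runs that failed (all-missing
#' columns) are dropped. The result is the input to the consensus methods.
#'
#' @param ensemble a (completed) [ClusterEnsemble-class].
#' @param k the cluster size slice to extract.
#' @return integer matrix `[n_samples x n_runs]` with an `"algorithm"`
#'   attribute naming each run's algorithm, and a `"k"` attribute.
#' @export
labelMatrix <- function(ensemble, k) {
  ki <- match(as.integer(k), ensemble@kValues)
  stopIfNot(!is.na(ki), "k = ", k, " is not in the ensemble")
  d <- dim(ensemble@labels)
  m <- matrix(ensemble@labels[, , , ki], nrow = d[1])
  algs <- rep(dimnames(ensemble@labels)[[3]], each = d[2])
  reps <- rep(dimnames(ensemble@labels)[[2]], times = d[3])
  keep <- colSums(!is.na(m)) > 0
  m <- m[, keep, drop = FALSE]
  stopIfNot(ncol(m) >= 1, "no successful runs at k = ", k)
  rownames(m) <- dimnames(ensemble@labels)[[1]]
  colnames(m) <- paste(algs[keep], reps[keep], sep = ".")
  attr(m, "algorithm") <- algs[keep]
  attr(m, "k") <- as.integer(k)
  m
}

#' Write / read a clustering array as long-format CSV
#'
#' One row per (sample, repetition, algorithm, k) cell; missing cells are
#' written with the sentinel label -1. This is the array's interchange
#' format.
#'
#' @param ensemble a [ClusterEnsemble-class].
#' @param path output CSV path.
#' @return `writeClusteringArray` returns `path` invisibly.
#' @export
writeClusteringArray <- function(ensemble, path) {
  dn <- dimnames(ensemble@labels)
  long <- expand.grid(
    sample = dn[[1]], rep = dn[[2]], algorithm = dn[[3]], k = dn[[4]],
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  long$label <- as.vector(ensemble@labels)
  long$label[is.na(long$label)] <- -1L
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
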