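## Consensus-matrix diagnostics and cluster validity indices.

#' Compute the consensus (co-clustering) matrix of a set of runs
#'
#' Entry (i, j) is the number of runs assigning samples i and j to the same
#' cluster divided by the number of runs in which both were assigned. With
#' a completed label matrix the denominator is the run count everywhere;
#' with a pre-completion slice, pairs never co-sampled get an undefined
#' (`NA`) entry, which CDF and PAC summaries exclude.
#'
#' @param lm integer label matrix (samples x runs), `NA` for unassigned.
#' @param weights optional per-run nonnegative weights; both the
#'   co-clustering and joint-assignment counts become weighted sums.
#' @return a [ConsensusMatrix-class].
#' @export
#' @examples
#' cm <- consensusMatrix(cbind(c(1, 1, 2), c(1, 2, 2)))
#' consensusValues(cm)
consensusMatrix <- function(lm, weights = NULL) {
  lm <- as.matrix(lm)
  n <- nrow(lm)
  nRuns <- ncol(lm)
  stopIfNot(nRuns >= 1, "need at least one run")
  if (is.null(weights)) weights <- rep(1, nRuns)
  stopIfNot(length(weights) == nRuns, "one weight per run required")
  stopIfNot(all(weights >= 0), "weights must be nonnegative")
  stopIfNot(sum(weights) > 0, "total weight must be positive")
  co <- matrix(0, n, n)
  joint <- matrix(0, n, n)
  for (j in seq_len(nRuns)) {
    lab <- lm[, j]
    ok <- !is.na(lab)
    same <- outer(lab, lab, "==")
    same[!ok, ] <- FALSE
    same[, !ok] <- FALSE
    co <- co + weights[j] * same
    joint <- joint + weights[j] * outer(ok, ok, "&")
  }
  values <- ifelse(joint > 0, co / joint, NA_real_)
  diag(values) <- 1
  dimnames(values) <- dimnames(co) <- dimnames(joint) <-
    list(rownames(lm), rownames(lm))
  k <- attr(lm, "k") %||% NA_integer_
  new("ConsensusMatrix",
    values = values, coCount = co, jointCount = joint,
    nRuns = as.integer(nRuns), k = as.integer(k)
  )
}

offDiagonal <- function(cm) {
  v <- cm@values[upper.tri(cm@values)]
  v[!is.na(v)]
}

#' Empirical CDF of consensus values
#'
#' The empirical cumulative distribution over the `n(n-1)/2` defined
#' off-diagonal (upper-triangle) consensus entries. A clean clustering
#' yields a near-two-point CDF (mass at 0 and 1); intermediate mass marks
#' ambiguity.
#'
#' @param cm a [ConsensusMatrix-class].
#' @return an `ecdf` step function, evaluable on `[0, 1]`, with the sorted
#'   entry values in attribute `"values"`.
#' @export
consensusCDF <- function(cm) {
  v <- offDiagonal(cm)
  stopIfNot(length(v) >= 1, "no defined off-diagonal consensus entries")
  f <- ecdf(v)
  attr(f, "values") <- sort(v)
  f
}

#' Relative change in area under the consensus CDF across k
#'
#' The area under an empirical CDF of values in `[0, 1]` is
#' `1 - mean(values)` (the exact step-function trapezoid). For the smallest
#' k the statistic is the area itself; for each subsequent k it is the
#' relative change versus the previous k.
#'
#' @param cdfs named list of CDFs from [consensusCDF()], names = k, in
#'   ascending k order.
#' @return named numeric vector of the per-k statistic (`NA` where the
#'   previous area is zero).
#' @export
deltaAUC <- function(cdfs) {
  stopIfNot(length(cdfs) >= 1, "need at least one CDF")
  areas <- vapply(cdfs, function(f) 1 - mean(attr(f, "values")), numeric(1))
  out <- areas
  if (length(areas) > 1) {
    for (i in 2:length(areas)) {
      out[i] <- if (areas[i - 1] > 0) {
        (areas[i] - areas[i - 1]) / areas[i - 1]
      } else {
        NA_real_
      }
    }
  }
  out
}

#' Proportion of ambiguous clustering (PAC)
#'
#' Fraction of defined off-diagonal consensus entries lying strictly inside
#' the open interval `(lower, upper)`. Entries exactly at a bound count as
#' unambiguous. Low PAC indicates a stable clustering.
#'
#' @param cm a [ConsensusMatrix-class].
#' @param lower,upper ambiguity bounds, defaults 0.05 and 0.95.
#' @return PAC in `[0, 1]`.
#' @export
pac <- function(cm, lower = 0.05, upper = 0.95) {
  stopIfNot(lower >= 0 && upper <= 1 && lower < upper, "need 0 <= lower < upper <= 1")
  v <- offDiagonal(cm)
  stopIfNot(length(v) >= 1, "no defined consensus entries")
  mean(v > lower & v < upper)
}

#' Select the cluster size with the smallest PAC
#'
#' @param pacPerK named numeric vector (names = k) of PAC values; `NA`
#'   entries are skipped.
#' @return the selected k (ties go to the smallest k).
#' @export
#' @examples
#' selectK(c(`2` = 0.4, `3` = 0.1, `4` = 0.25))
selectK <- function(pacPerK) {
  ks <- as.integer(names(pacPerK))
  stopIfNot(!anyNA(ks), "pacPerK must be named by k")
  ok <- !is.na(pacPerK)
  stopIfNot(any(ok), "all PAC values undefined")
  ks <- ks[ok]
  p <- pacPerK[ok]
  ord <- order(p, ks) # ties -> smallest k
  ks[ord[1]]
}

## ---------------------------------------------------------------------------
## internal validity indices

#' Names and optimisation directions of the internal validity indices
#'
#' @return data frame with columns `index` and `direction`
#'   (`"maximize"`/`"minimize"`) for the default thirteen-index suite.
#' @export
internalIndexRegistry <- function() {
  data.frame(
    index = c(
      "calinski_harabasz", "dunn", "pbm", "tau", "gamma", "c_index",
      "davies_bouldin", "mcclain_rao", "sd_dis", "ray_turi", "g_plus",
      "silhouette", "compactness"
    ),
    direction = c(
      "maximize", "maximize", "maximize", "maximize", "maximize", "minimize",
      "minimize", "minimize", "minimize", "minimize", "minimize",
      "maximize", "minimize"
    ),
    stringsAsFactors = FALSE
  )
}

#' Internal validity indices of a partition
#'
#' Computes compactness/separation indices of a partition of the data:
#' Calinski-Harabasz, Dunn, PBM, tau, gamma, C-index, Davies-Bouldin,
#' McClain-Rao, the SD separation component, Ray-Turi, G-plus, mean
#' silhouette width and compactness (mean distance to the own-cluster
#' centroid), each tagged with its optimisation direction. Indices
#' undefined for the input (single cluster, zero denominators) are returned
#' as non-finite flagged values rather than errors.
#'
#' @param x prepared numeric matrix (samples x features).
#' @param labels integer partition of the rows.
#' @param indexSet index names to compute (default: all thirteen).
#' @return data frame with columns `index`, `score`, `direction`.
#' @export
internalIndices <- function(x, labels, indexSet = internalIndexRegistry()$index) {
  reg <- internalIndexRegistry()
  unknown <- setdiff(indexSet, reg$index)
  stopIfNot(!length(unknown), "unknown index name(s): ", paste(unknown, collapse = ", "))
  x <- as.matrix(x)
  labels <- denseLabels(labels)
  n <- nrow(x)
  stopIfNot(length(labels) == n, "one label per sample required")
  k <- max(labels)
  cl <- split(seq_len(n), labels)
  dmat <- as.matrix(dist(x))
  within <- outer(labels, labels, "==")
  ut <- upper.tri(dmat)
  dW <- dmat[ut & within] # within-cluster distances
  dB <- dmat[ut & !within] # between-cluster distances
  centroids <- do.call(rbind, lapply(cl, function(i) colMeans(x[i, , drop = FALSE])))
  grand <- colMeans(x)
  distToOwn <- sqrt(rowSums((x - centroids[labels, , drop = FALSE])^2))
  distToGrand <- sqrt(rowSums(sweep(x, 2, grand)^2))
  W <- sum(distToOwn^2)
  B <- sum(lengths(cl) * rowSums(sweep(centroids, 2, grand)^2))
  centD <- as.matrix(dist(centroids))
  centOff <- centD[upper.tri(centD)]
  multi <- k >= 2 && length(dB) > 0

  # concordance counts between within- and between-cluster distances
  concordance <- function() {
    if (!multi || !length(dW)) {
      return(c(sPlus = NA_real_, sMinus = NA_real_))
    }
    bs <- sort(dB)
    le <- findInterval(dW, bs) # b <= w
    lt <- findInterval(dW, bs, left.open = TRUE) # b < w
    c(sPlus = sum(length(bs) - le), sMinus = sum(lt))
  }
  conc <- concordance()
  nw <- length(dW)
  nb <- length(dB)
  nd <- nw + nb

  val <- function(name) {
    switch(name,
      calinski_harabasz = if (multi && k < n && W > 0) {
        (B / (k - 1)) / (W / (n - k))
      } else {
        NA_real_
      },
      dunn = if (multi) {
        maxDiam <- max(c(dW, 0))
        if (maxDiam == 0) Inf else min(dB) / maxDiam
      } else {
        NA_real_
      },
      pbm = if (multi) {
        ew <- sum(distToOwn)
        if (ew == 0) Inf else ((1 / k) * (sum(distToGrand) / ew) * max(centOff))^2
      } else {
        NA_real_
      },
      tau = if (multi && nw > 0) unname((conc["sPlus"] - conc["sMinus"]) / (nw * nb)) else NA_real_,
      gamma = if (multi && nw > 0 && sum(conc) > 0) {
        unname((conc["sPlus"] - conc["sMinus"]) / (conc["sPlus"] + conc["sMinus"]))
      } else {
        NA_real_
      },
      c_index = if (multi && nw > 0) {
        ds <- sort(dmat[ut])
        smin <- sum(ds[seq_len(nw)])
        smax <- sum(ds[seq.int(nd - nw + 1, nd)])
        if (smax > smin) (sum(dW) - smin) / (smax - smin) else NA_real_
      } else {
        NA_real_
      },
      davies_bouldin = if (multi) {
        s <- vapply(seq_len(k), function(j) mean(distToOwn[labels == j]), numeric(1))
        mean(vapply(seq_len(k), function(i) {
          max(vapply(
            setdiff(seq_len(k), i),
            function(j) (s[i] + s[j]) / centD[i, j], numeric(1)
          ))
        }, numeric(1)))
      } else {
        NA_real_
      },
      mcclain_rao = if (multi && nw > 0 && mean(dB) > 0) mean(dW) / mean(dB) else NA_real_,
      sd_dis = if (multi) {
        dmin <- min(centOff)
        if (dmin == 0) Inf else {
          (max(centOff) / dmin) *
            sum(1 / rowSums(centD)[seq_len(k)])
        }
      } else {
        NA_real_
      },
      ray_turi = if (multi) {
        dmin2 <- min(centOff)^2
        if (dmin2 == 0) Inf else (W / n) / dmin2
      } else {
        NA_real_
      },
      g_plus = if (multi && nw > 0) {
        unname(2 * conc["sMinus"] / (nd * (nd - 1)))
      } else {
        NA_real_
      },
      silhouette = if (multi) {
        sil <- cluster::silhouette(labels, dmatrix = dmat)
        # silhouette() degenerates to a bare vector when every cluster is
        # a singleton; the index is undefined there
        if (is.matrix(sil)) mean(sil[, "sil_width"]) else NA_real_
      } else {
        NA_real_
      },
      compactness = mean(distToOwn)
    )
  }
  scores <- vapply(indexSet, val, numeric(1))
  data.frame(
    index = indexSet,
    score = unname(scores),
    direction = reg$direction[match(indexSet, reg$index)],
    stringsAsFactors = FALSE
  )
}

## ---------------------------------------------------------------------------
## external validity indices

entropyOf <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' External validity indices against reference labels
#'
#' Adjusted Rand index (hypergeometric permutation-model correction),
#' normalised mutual information (normalised by the mean of the two
#' entropies) and classification accuracy after optimal (Hungarian)
#' relabelling.
#'
#' @param labels integer partition.
#' @param reference integer reference partition (same length).
#' @return named numeric vector `c(ari, nmi, accuracy)`.
#' @export
#' @examples
#' externalIndices(c(1, 1, 2, 2), c(2, 2, 1, 1))
externalIndices <- function(labels, reference) {
  stopIfNot(length(labels) == length(reference), "partitions differ in length")
  labels <- denseLabels(labels)
  reference <- denseLabels(reference)
  n <- length(labels)
  tab <- table(labels, reference)
  a <- rowSums(tab)
  b <- colSums(tab)
  choose2 <- function(v) sum(v * (v - 1) / 2)
  sumComb <- choose2(as.vector(tab))
  expected <- choose2(a) * choose2(b) / (n * (n - 1) / 2)
  maxComb <- (choose2(a) + choose2(b)) / 2
  ari <- if (maxComb == expected) 1 else (sumComb - expected) / (maxComb - expected)
  p <- tab / n
  mi <- 0
  pr <- a / n
  pc <- b / n
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (pr[i] * pc[j]))
    }
  }
  h1 <- entropyOf(pr)
  h2 <- entropyOf(pc)
  nmi <- if (h1 + h2 == 0) 1 else mi / ((h1 + h2) / 2)
  acc <- mean(relabelPartition(labels, reference) == reference)
  c(ari = unname(ari), nmi = unname(nmi), accuracy = unname(acc))
}
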