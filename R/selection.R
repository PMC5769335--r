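## Algorithm selection: rank algorithms across validity indices, trim the
## ensemble to the top N, and compute evaluation-proportional weights.

#' Assemble a validity table
#'
#' @param scores numeric matrix, rows = algorithms (rownames required),
#'   columns = index names. Non-finite cells are treated as undefined.
#' @param directions named character vector (`"maximize"`/`"minimize"`) per
#'   index column; defaults to the internal index registry directions.
#' @return the matrix with a `"direction"` attribute, class `validityTable`.
#' @export
validityTable <- function(scores, directions = NULL) {
  scores <- as.matrix(scores)
  stopIfNot(!is.null(rownames(scores)), "scores must have algorithm rownames")
  stopIfNot(!is.null(colnames(scores)), "scores must have index colnames")
  if (is.null(directions)) {
    reg <- internalIndexRegistry()
    directions <- setNames(reg$direction, reg$index)[colnames(scores)]
  }
  stopIfNot(
    !anyNA(directions) && all(colnames(scores) %in% names(directions)),
    "every index column needs a direction"
  )
  stopIfNot(
    all(directions[colnames(scores)] %in% c("maximize", "minimize")),
    "directions must be 'maximize' or 'minimize'"
  )
  structure(scores,
    direction = directions[colnames(scores)],
    class = c("validityTable", class(scores))
  )
}

## per-index ranks, best first, honoring direction; undefined cells -> NA
indexRanks <- function(vt) {
  dirs <- attr(vt, "direction")
  apply2 <- function(j) {
    v <- vt[, j]
    v[!is.finite(v)] <- NA
    if (dirs[j] == "maximize") v <- -v
    r <- rank(v, ties.method = "average", na.last = "keep")
    r
  }
  ranks <- vapply(seq_len(ncol(vt)), apply2, numeric(nrow(vt)))
  dimnames(ranks) <- dimnames(vt)
  ranks
}

footruleCost <- function(ordering, ranks) {
  # ordering: algorithm names best-first; cost = total footrule distance to
  # each index's rank list, undefined cells skipped
  pos <- match(rownames(ranks), ordering)
  sum(abs(ranks - pos), na.rm = TRUE)
}

#' Rank algorithms by aggregating validity-index rankings
#'
#' Each index ranks the algorithms best-first (honoring its optimisation
#' direction; undefined cells are excluded from that index's ranking). The
#' per-index rankings are aggregated either by Borda count (order by mean
#' rank, ties broken alphabetically) or by a seeded Monte-Carlo search for
#' the ordering minimising the total Spearman footrule distance to the
#' per-index rank lists.
#'
#' @param vt a [validityTable()] (algorithms x indices).
#' @param aggregation `"borda"` (default) or `"footrule_mc"`.
#' @param mcSamples Monte-Carlo candidate count for `"footrule_mc"`.
#' @param seed seed for the Monte-Carlo search.
#' @return character vector of algorithm names, best first.
#' @export
rankAlgorithms <- function(vt, aggregation = c("borda", "footrule_mc"),
                           mcSamples = 2000, seed = 1) {
  aggregation <- match.arg(aggregation)
  stopIfNot(any(is.finite(vt)), "all validity cells are undefined")
  ranks <- indexRanks(vt)
  meanRank <- rowMeans(ranks, na.rm = TRUE)
  meanRank[is.nan(meanRank)] <- nrow(vt) # algorithm undefined everywhere: last
  borda <- rownames(vt)[order(meanRank, rownames(vt))]
  if (aggregation == "borda") {
    return(borda)
  }
  # footrule_mc: seeded stochastic search seeded from the Borda order
  best <- borda
  bestCost <- footruleCost(best, ranks)
  m <- nrow(vt)
  withSeed(seed, {
    current <- best
    currentCost <- bestCost
    for (s in seq_len(mcSamples)) {
      cand <- if (s %% 20 == 0) {
        sample(rownames(vt)) # occasional random restart
      } else {
        swap <- sample(m, 2)
        tmp <- current
        tmp[swap] <- tmp[rev(swap)]
        tmp
      }
      cost <- footruleCost(cand, ranks)
      if (cost <= currentCost) { # plateau walks allowed
        current <- cand
        currentCost <- cost
      }
      if (cost < bestCost) {
        best <- cand
        bestCost <- cost
      }
    }
  })
  best
}

#' Restrict an ensemble to the top N ranked algorithms
#'
#' Keeps only the label slices of the `topN` best algorithms; labels and
#' subsample provenance are unchanged.
#'
#' @param ensemble a [ClusterEnsemble-class].
#' @param ranking character vector of algorithm names, best first.
#' @param topN how many algorithms to keep.
#' @return the trimmed [ClusterEnsemble-class].
#' @export
trimEnsemble <- function(ensemble, ranking, topN) {
  algs <- algorithmNames(ensemble)
  stopIfNot(all(ranking %in% algs), "ranking names algorithms not in the ensemble")
  stopIfNot(topN >= 1 && topN <= length(ranking), "topN must be in 1..length(ranking)")
  keep <- ranking[seq_len(topN)]
  idx <- sort(match(keep, algs)) # preserve original slice order
  initialize(ensemble, labels = ensemble@labels[, , idx, , drop = FALSE])
}

#' Evaluation-proportional algorithm weights
#'
#' Each index column is min-max rescaled to `[0, 1]` (minimise-direction
#' columns flipped so larger is always better); an algorithm's score is its
#' mean over defined indices, and weights are scores normalised to sum 1.
#'
#' @param vt a [validityTable()].
#' @return named numeric weight vector summing to 1.
#' @export
computeWeights <- function(vt) {
  stopIfNot(any(is.finite(vt)), "all validity cells are undefined")
  dirs <- attr(vt, "direction")
  scaled <- vt
  for (j in seq_len(ncol(vt))) {
    v <- vt[, j]
    v[!is.finite(v)] <- NA
    rng <- range(v, na.rm = TRUE)
    v <- if (diff(rng) == 0) ifelse(is.na(v), NA, 0.5) else (v - rng[1]) / diff(rng)
    if (dirs[j] == "minimize") v <- 1 - v
    scaled[, j] <- v
  }
  score <- rowMeans(scaled, na.rm = TRUE)
  score[is.nan(score)] <- 0
  if (sum(score) == 0) {
    warning("all algorithm scores are zero; using uniform weights")
    score <- rep(1, nrow(vt))
  }
  w <- score / sum(score)
  names(w) <- rownames(vt)
  w
}

#' Weighted consensus matrix
#'
#' Consensus matrix whose runs are weighted by their algorithm's weight:
#' entry (i, j) is the weighted proportion of runs co-clustering the pair,
#' among the weighted runs assigning both.
#'
#' @param lm label matrix from [labelMatrix()] (carries each run's
#'   algorithm in the `"algorithm"` attribute).
#' @param weights named per-algorithm weights covering every algorithm
#'   present.
#' @return a [ConsensusMatrix-class].
#' @export
weightedConsensusMatrix <- function(lm, weights) {
  algs <- attr(lm, "algorithm")
  stopIfNot(!is.null(algs), "lm must carry its runs' algorithms (see labelMatrix)")
  stopIfNot(
    all(algs %in% names(weights)),
    "weights missing for: ", paste(setdiff(algs, names(weights)), collapse = ", ")
  )
  consensusMatrix(lm, weights = unname(weights[algs]))
}
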