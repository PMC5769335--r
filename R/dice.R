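## The pipeline driver: diverse generation -> completion -> evaluation ->
## algorithm trimming/weighting -> PAC-based k selection -> consensus
## formation -> validation and significance testing.

diceLog <- function(verbose, stage, ...) {
  if (verbose) {
    message(format(Sys.time(), "[%H:%M:%S] "), "[", stage, "] ", ...)
  }
}

#' Run the full diverse cluster ensemble pipeline
#'
#' Chains every stage: prepares the data, generates the clustering array
#' over algorithms, cluster sizes and 80% subsamples, completes it by
#' k-nearest-neighbour voting, scores every base algorithm with the
#' internal validity indices, aggregates the index rankings to trim the
#' ensemble to the best algorithms (and optionally weight them), selects
#' the cluster number by minimum PAC, combines the trimmed array with the
#' configured consensus methods, evaluates the ensemble solutions with the
#' same indices (plus external indices when reference labels are given) and
#' optionally tests cluster significance against a Gaussian null. The whole
#' run is reproducible from `seed`.
#'
#' @param x numeric matrix, samples in rows.
#' @param kValues candidate cluster sizes, default `2:4`.
#' @param algorithms algorithm registry, default [builtinAlgorithms()].
#' @param reps subsample repetitions, default 10.
#' @param fraction observation fraction per subsample, default 0.8.
#' @param knnK completion neighbourhood size, default 5.
#' @param methods consensus methods to run, default all of
#'   [consensusMethods()].
#' @param trimN keep only this many top-ranked algorithms (`NULL` = keep
#'   all).
#' @param reweigh weight runs by their algorithm's validity scores when
#'   building consensus matrices?
#' @param aggregation rank-aggregation scheme for [rankAlgorithms()].
#' @param pacLower,pacUpper PAC ambiguity bounds, defaults 0.05 / 0.95.
#' @param dc LCE decay constant, default 0.8.
#' @param pinK pin the cluster size instead of selecting by PAC.
#' @param referenceLabels optional reference partition for external indices.
#' @param sigclustSims Monte-Carlo simulations for the significance tests
#'   (0 disables them).
#' @param scale,topVarFeatures,imputeMissing forwarded to [prepareMatrix()].
#' @param seed integer master seed.
#' @param outputDir optional directory; when set, all stage outputs are
#'   persisted there ([writeDiceResult()]).
#' @param verbose log stage progress messages?
#' @return a [DiceResult-class].
#' @export
dice <- function(x, kValues = 2:4, algorithms = builtinAlgorithms(),
                 reps = 10, fraction = 0.8, knnK = 5,
                 methods = consensusMethods(), trimN = NULL, reweigh = FALSE,
                 aggregation = c("borda", "footrule_mc"),
                 pacLower = 0.05, pacUpper = 0.95, dc = 0.8,
                 pinK = NULL, referenceLabels = NULL, sigclustSims = 0,
                 scale = FALSE, topVarFeatures = NULL, imputeMissing = FALSE,
                 seed = 1, outputDir = NULL, verbose = FALSE) {
  aggregation <- match.arg(aggregation)
  stopIfNot(length(methods) >= 1, "configure at least one consensus method")
  stopIfNot(
    all(methods %in% consensusMethods()),
    "unknown consensus method(s): ",
    paste(setdiff(methods, consensusMethods()), collapse = ", ")
  )
  stopIfNot(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  if (!is.null(pinK)) stopIfNot(pinK %in% kValues, "pinK must be one of kValues")

  diceLog(verbose, "prepare", "preparing ", nrow(x), " x ", ncol(x), " matrix")
  x <- prepareMatrix(x,
    scale = scale, topVarFeatures = topVarFeatures,
    imputeMissing = imputeMissing
  )
  kValues <- as.integer(sort(unique(kValues)))

  diceLog(
    verbose, "generate", length(algorithms), " algorithms x ", reps,
    " reps x ", length(kValues), " cluster sizes"
  )
  ensemble <- generateArray(x, kValues,
    algorithms = algorithms, reps = reps,
    fraction = fraction, seed = seed
  )
  diceLog(verbose, "complete", "k-nearest-neighbour completion (knnK = ", knnK, ")")
  ensemble <- completeByKNN(ensemble, knnK = knnK, skipEmpty = TRUE)

  # internal indices per (algorithm, k): each algorithm's partition at a k
  # is the majority vote of its own repetitions
  diceLog(verbose, "evaluate", "internal validity indices per algorithm and k")
  algNames <- algorithmNames(ensemble)
  reg <- internalIndexRegistry()
  validity <- list()
  perAlgLabels <- list()
  for (k in kValues) {
    lm <- labelMatrix(ensemble, k)
    runAlg <- attr(lm, "algorithm")
    for (alg in algNames) {
      cols <- which(runAlg == alg)
      if (!length(cols)) next
      sub <- lm[, cols, drop = FALSE]
      attr(sub, "k") <- k
      sol <- majorityVote(sub, k)
      perAlgLabels[[paste(alg, k, sep = ".")]] <- clusterLabels(sol)
      sc <- internalIndices(x, clusterLabels(sol))
      validity[[length(validity) + 1]] <- data.frame(
        entity = alg, k = k, sc,
        stringsAsFactors = FALSE
      )
    }
  }
  validity <- do.call(rbind, validity)

  # rank once across all k: each algorithm represented per index by its
  # best score over k
  bestScores <- sapply(reg$index, function(ix) {
    vapply(algNames, function(alg) {
      v <- validity$score[validity$entity == alg & validity$index == ix]
      v <- v[is.finite(v)]
      if (!length(v)) {
        return(NA_real_)
      }
      dir <- reg$direction[reg$index == ix]
      if (dir == "maximize") max(v) else min(v)
    }, numeric(1))
  })
  bestScores <- matrix(bestScores,
    nrow = length(algNames),
    dimnames = list(algNames, reg$index)
  )
  vt <- validityTable(bestScores)
  ranking <- rankAlgorithms(vt,
    aggregation = aggregation,
    seed = deriveSeed(seed, "rank")
  )
  diceLog(verbose, "rank", paste(ranking, collapse = " > "))

  trimmed <- ensemble
  if (!is.null(trimN) && trimN < length(ranking)) {
    diceLog(verbose, "trim", "keeping top ", trimN, " algorithms")
    trimmed <- trimEnsemble(ensemble, ranking, trimN)
  }
  weights <- numeric(0)
  if (reweigh) {
    keep <- algorithmNames(trimmed)
    weights <- computeWeights(validityTable(
      bestScores[keep, , drop = FALSE]
    ))
    diceLog(verbose, "weigh", paste(sprintf("%s=%.3f", names(weights), weights),
      collapse = ", "
    ))
  }

  # PAC per k on the (possibly trimmed, possibly weighted) ensemble
  diceLog(verbose, "pac", "consensus matrices and PAC across k")
  cms <- list()
  pacPerK <- setNames(rep(NA_real_, length(kValues)), as.character(kValues))
  for (k in kValues) {
    lm <- labelMatrix(trimmed, k)
    cms[[as.character(k)]] <- if (length(weights)) {
      weightedConsensusMatrix(lm, weights)
    } else {
      consensusMatrix(lm)
    }
    pacPerK[as.character(k)] <- pac(cms[[as.character(k)]], pacLower, pacUpper)
  }
  cdfs <- lapply(cms, consensusCDF)
  dAUC <- deltaAUC(cdfs)
  kSel <- if (!is.null(pinK)) as.integer(pinK) else selectK(pacPerK)
  diceLog(verbose, "select_k", "selected k = ", kSel, if (!is.null(pinK)) " (pinned)" else "")

  # consensus formation at the selected k
  lmSel <- labelMatrix(trimmed, kSel)
  cmSel <- cms[[as.character(kSel)]]
  solutions <- list()
  for (m in methods) {
    diceLog(verbose, "consensus", m)
    solutions[[m]] <- runConsensus(m, lmSel,
      k = kSel,
      seed = deriveSeed(seed, "consensus", m), dc = dc, cm = cmSel
    )
  }

  # evaluate ensemble solutions with the same indices
  for (m in methods) {
    sol <- solutions[[m]]
    if (sol@degenerate) next
    sc <- internalIndices(x, clusterLabels(sol))
    validity <- rbind(validity, data.frame(
      entity = paste0("ensemble_", m), k = kSel, sc,
      stringsAsFactors = FALSE
    ))
  }

  if (!is.null(referenceLabels)) {
    diceLog(verbose, "external", "external indices against reference labels")
    stopIfNot(
      length(referenceLabels) == nrow(x),
      "referenceLabels must have one label per sample"
    )
    ref <- denseLabels(as.integer(factor(referenceLabels)))
    for (m in methods) {
      ext <- externalIndices(clusterLabels(solutions[[m]]), ref)
      validity <- rbind(validity, data.frame(
        entity = paste0("ensemble_", m), k = kSel,
        index = names(ext), score = unname(ext), direction = "maximize",
        stringsAsFactors = FALSE
      ))
    }
  }

  significance <- data.frame(
    comparison = character(), observed_ci = numeric(),
    p_value = numeric(), n_sim = integer()
  )
  if (sigclustSims > 0) {
    diceLog(verbose, "sigclust", "Gaussian-null significance tests (", sigclustSims, " sims)")
    finalLabels <- clusterLabels(solutions[[methods[1]]])
    significance <- significanceDriver(x, finalLabels,
      nSim = sigclustSims,
      seed = deriveSeed(seed, "sigclust")
    )
  }

  config <- list(
    kValues = kValues, algorithms = algNames, reps = reps,
    fraction = fraction, knnK = knnK, methods = methods,
    trimN = trimN, reweigh = reweigh, aggregation = aggregation,
    pacLower = pacLower, pacUpper = pacUpper, dc = dc, pinK = pinK,
    sigclustSims = sigclustSims, scale = scale,
    topVarFeatures = topVarFeatures, seed = seed,
    nSamples = nrow(x), nFeatures = ncol(x),
    failures = ensemble@failures
  )
  result <- new("DiceResult",
    selectedK = kSel, solutions = solutions, consensusMatrices = cms,
    pac = pacPerK, deltaAUC = dAUC, validity = validity,
    ranking = ranking, weights = weights, significance = significance,
    config = config
  )
  if (!is.null(outputDir)) writeDiceResult(result, outputDir)
  result
}
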