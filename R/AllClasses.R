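## Central S4 containers. The clustering substrate itself is a plain numeric
## matrix (samples x features, rownames = sample IDs, colnames = feature IDs),
## the convention of the field's clustering stack; the ensemble-specific
## objects below carry the structure a plain matrix cannot.

#' ClusterEnsemble: the diverse clustering array
#'
#' Four-dimensional integer label array indexed (sample, repetition,
#' algorithm, k), produced by [generateArray()]. `NA` marks a sample not
#' drawn in that repetition's subsample (or an algorithm run that failed).
#' After [completeByKNN()] the array has no missing cells and `completed`
#' is `TRUE`.
#'
#' @slot labels integer array `[n_samples, reps, n_algorithms, n_k]`, with
#'   `dimnames` giving sample IDs, repetition names, algorithm names and k
#'   values.
#' @slot kValues integer vector of requested cluster sizes.
#' @slot subsamples list of integer index vectors, one per repetition: the
#'   samples drawn for that repetition.
#' @slot completed logical; `TRUE` once missing cells have been filled in.
#' @slot data the prepared numeric data matrix the array was generated from
#'   (kept for k-nearest-neighbour completion and validity indices).
#' @slot failures character vector describing algorithm runs that failed.
#' @exportClass ClusterEnsemble
setClass("ClusterEnsemble",
  representation(
    labels = "array",
    kValues = "integer",
    subsamples = "list",
    completed = "logical",
    data = "matrix",
    failures = "character"
  )
)

setValidity("ClusterEnsemble", function(object) {
  d <- dim(object@labels)
  if (length(d) != 4) return("labels must be a 4-d array (sample, rep, algorithm, k)")
  if (length(object@kValues) != d[4]) return("kValues length must match dim 4 of labels")
  if (length(object@subsamples) != d[2]) return("one subsample index set per repetition required")
  if (nrow(object@data) != d[1]) return("data rows must match dim 1 of labels")
  for (ki in seq_along(object@kValues)) {
    slice <- object@labels[, , , ki, drop = FALSE]
    vals <- slice[!is.na(slice)]
    if (length(vals) && (any(vals < 1L) || any(vals > object@kValues[ki]))) {
      return(sprintf("labels in k-slice %d outside 1..%d", object@kValues[ki], object@kValues[ki]))
    }
  }
  if (object@completed && anyNA(object@labels)) {
    return("completed ensemble must not contain missing labels")
  }
  TRUE
})

#' ConsensusMatrix: pairwise co-clustering proportions
#'
#' Symmetric `n x n` matrix whose entry (i, j) is the proportion of ensemble
#' runs clustering samples i and j together, among runs where both were
#' assigned. `coCount` and `jointCount` keep the numerator/denominator
#' provenance; entries with `jointCount` 0 (possible only before completion)
#' are `NA` and excluded from CDF and PAC summaries.
#'
#' @slot values numeric matrix in `[0, 1]`, unit diagonal.
#' @slot coCount,jointCount integer matrices (numerator / denominator).
#' @slot nRuns number of runs combined.
#' @slot k the cluster size of the combined slice (`NA` if mixed).
#' @exportClass ConsensusMatrix
setClass("ConsensusMatrix",
  representation(
    values = "matrix",
    coCount = "matrix",
    jointCount = "matrix",
    nRuns = "integer",
    k = "integer"
  )
)

setValidity("ConsensusMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (!isTRUE(all.equal(v, t(v), check.attributes = FALSE))) return("values must be symmetric")
  if (any(diag(v) != 1)) return("diagonal must be 1")
  ok <- v[!is.na(v)]
  if (length(ok) && (any(ok < 0) || any(ok > 1))) return("entries must lie in [0, 1]")
  TRUE
})

#' EnsembleSolution: one consensus partition
#'
#' @slot method one of `"majority_voting"`, `"kmodes"`, `"CSPA"`, `"LCE"`.
#' @slot labels named integer vector of cluster assignments in `1..k`.
#' @slot k the target cluster count.
#' @slot degenerate `TRUE` when fewer than `k` clusters are non-empty (for
#'   `k >= 2`); degenerate solutions are flagged, not errors, so the pipeline
#'   can skip them in evaluation.
#' @exportClass EnsembleSolution
setClass("EnsembleSolution",
  representation(
    method = "character",
    labels = "integer",
    k = "integer",
    degenerate = "logical"
  )
)

setValidity("EnsembleSolution", function(object) {
  if (any(object@labels < 1L | object@labels > object@k)) {
    return("labels must lie in 1..k")
  }
  TRUE
})

#' DiceResult: output of the full ensemble pipeline
#'
#' @slot selectedK cluster size chosen by minimum PAC (or pinned by the user).
#' @slot solutions list of [EnsembleSolution-class] objects at `selectedK`,
#'   one per configured consensus method.
#' @slot consensusMatrices list of [ConsensusMatrix-class], one per k.
#' @slot pac named numeric vector: PAC per k.
#' @slot deltaAUC named numeric vector: relative change in CDF area per k.
#' @slot validity data frame of internal (and any external) index scores for
#'   base algorithms and ensemble methods, with a `direction` attribute.
#' @slot ranking character vector: algorithms best-first by rank aggregation.
#' @slot weights named numeric algorithm weights (sum 1), or empty.
#' @slot significance data frame of cluster-significance tests
#'   (comparison, observed_ci, p_value, n_sim), possibly empty.
#' @slot config list echoing the full configuration, seeds included.
#' @exportClass DiceResult
setClass("DiceResult",
  representation(
    selectedK = "integer",
    solutions = "list",
    consensusMatrices = "list",
    pac = "numeric",
    deltaAUC = "numeric",
    validity = "data.frame",
    ranking = "character",
    weights = "numeric",
    significance = "data.frame",
    config = "list"
  )
)

#' @describeIn ClusterEnsemble-class display a summary
#' @param object a `ClusterEnsemble`
#' @export
setMethod("show", "ClusterEnsemble", function(object) {
  d <- dim(object@labels)
  cat(sprintf(
    "ClusterEnsemble: %d samples x %d reps x %d algorithms x %d cluster sizes\n",
    d[1], d[2], d[3], d[4]
  ))
  cat("  algorithms:", paste(dimnames(object@labels)[[3]], collapse = ", "), "\n")
  cat("  k values:", paste(object@kValues, collapse = ", "), "\n")
  cat("  completed:", object@completed)
  if (length(object@failures)) {
    cat(sprintf("  (%d failed runs)", length(object@failures)))
  }
  cat("\n")
})

#' @describeIn ConsensusMatrix-class display a summary
#' @param object a `ConsensusMatrix`
#' @export
setMethod("show", "ConsensusMatrix", function(object) {
  cat(sprintf(
    "ConsensusMatrix: %d samples, %d runs, k = %s\n",
    nrow(object@values), object@nRuns,
    if (is.na(object@k)) "mixed" else object@k
  ))
  off <- object@values[upper.tri(object@values)]
  cat(sprintf(
    "  off-diagonal mean %.3f (%d undefined entries)\n",
    mean(off, na.rm = TRUE), sum(is.na(off))
  ))
})

#' @describeIn EnsembleSolution-class display a summary
#' @param object an `EnsembleSolution`
#' @export
setMethod("show", "EnsembleSolution", function(object) {
  sizes <- table(factor(object@labels, levels = seq_len(object@k)))
  cat(sprintf(
    "EnsembleSolution [%s], k = %d%s\n  cluster sizes: %s\n",
    object@method, object@k,
    if (object@degenerate) " (degenerate)" else "",
    paste(as.integer(sizes), collapse = ", ")
  ))
})

#' @describeIn DiceResult-class display a summary
#' @param object a `DiceResult`
#' @export
setMethod("show", "DiceResult", function(object) {
  cat(sprintf("DiceResult: selected k = %d\n", object@selectedK))
  cat("  PAC per k:", paste(sprintf("%s=%.3f", names(object@pac), object@pac),
    collapse = ", "
  ), "\n")
  cat("  consensus methods:", paste(names(object@solutions), collapse = ", "), "\n")
  if (length(object@ranking)) {
    cat("  algorithm ranking:", paste(object@ranking, collapse = " > "), "\n")
  }
  if (nrow(object@significance)) {
    cat(sprintf("  significance tests: %d\n", nrow(object@significance)))
  }
})
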