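#' Accessors for ensemble objects
#'
#' `clusterLabels` returns the label container (the 4-d array of a
#' [ClusterEnsemble-class], or the assignment vector of an
#' [EnsembleSolution-class]); `kValues` the cluster sizes; `algorithmNames`
#' the algorithm dimension; `isCompleted` whether missing cells have been
#' filled; `consensusValues` the numeric matrix of a
#' [ConsensusMatrix-class]; `selectedK`, `pacScores`, `ensembleSolutions`,
#' `validityScores`, `algorithmRanking`, `algorithmWeights` and
#' `significanceTable` the corresponding [DiceResult-class] components.
#'
#' @param x the object.
#' @return The slot contents; see above.
#' @name ensemble-accessors
#' @aliases clusterLabels kValues algorithmNames isCompleted consensusValues
#'   selectedK pacScores ensembleSolutions validityScores algorithmRanking
#'   algorithmWeights significanceTable
NULL

#' @rdname ensemble-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname ensemble-accessors
#' @export
setGeneric("kValues", function(x) standardGeneric("kValues"))
#' @rdname ensemble-accessors
#' @export
setGeneric("algorithmNames", function(x) standardGeneric("algorithmNames"))
#' @rdname ensemble-accessors
#' @export
setGeneric("isCompleted", function(x) standardGeneric("isCompleted"))
#' @rdname ensemble-accessors
#' @export
setGeneric("consensusValues", function(x) standardGeneric("consensusValues"))
#' @rdname ensemble-accessors
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))
#' @rdname ensemble-accessors
#' @export
setGeneric("pacScores", function(x) standardGeneric("pacScores"))
#' @rdname ensemble-accessors
#' @export
setGeneric("ensembleSolutions", function(x) standardGeneric("ensembleSolutions"))
#' @rdname ensemble-accessors
#' @export
setGeneric("validityScores", function(x) standardGeneric("validityScores"))
#' @rdname ensemble-accessors
#' @export
setGeneric("algorithmRanking", function(x) standardGeneric("algorithmRanking"))
#' @rdname ensemble-accessors
#' @export
setGeneric("algorithmWeights", function(x) standardGeneric("algorithmWeights"))
#' @rdname ensemble-accessors
#' @export
setGeneric("significanceTable", function(x) standardGeneric("significanceTable"))

#' @rdname ensemble-accessors
setMethod("clusterLabels", "ClusterEnsemble", function(x) x@labels)
#' @rdname ensemble-accessors
setMethod("clusterLabels", "EnsembleSolution", function(x) x@labels)
#' @rdname ensemble-accessors
setMethod("kValues", "ClusterEnsemble", function(x) x@kValues)
#' @rdname ensemble-accessors
setMethod("kValues", "EnsembleSolution", function(x) x@k)
#' @rdname ensemble-accessors
setMethod("algorithmNames", "ClusterEnsemble", function(x) dimnames(x@labels)[[3]])
#' @rdname ensemble-accessors
setMethod("isCompleted", "ClusterEnsemble", function(x) x@completed)
#' @rdname ensemble-accessors
setMethod("consensusValues", "ConsensusMatrix", function(x) x@values)
#' @rdname ensemble-accessors
setMethod("selectedK", "DiceResult", function(x) x@selectedK)
#' @rdname ensemble-accessors
setMethod("pacScores", "DiceResult", function(x) x@pac)
#' @rdname ensemble-accessors
setMethod("ensembleSolutions", "DiceResult", function(x) x@solutions)
#' @rdname ensemble-accessors
setMethod("validityScores", "DiceResult", function(x) x@validity)
#' @rdname ensemble-accessors
setMethod("algorithmRanking", "DiceResult", function(x) x@ranking)
#' @rdname ensemble-accessors
setMethod("algorithmWeights", "DiceResult", function(x) x@weights)
#' @rdname ensemble-accessors
setMethod("significanceTable", "DiceResult", function(x) x@significance)

#' @rdname ensemble-accessors
#' @export
setMethod("as.matrix", "ConsensusMatrix", function(x) x@values)
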