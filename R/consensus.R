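## Consensus formation: combine one k-slice of the completed clustering
## array (a samples x runs label matrix) into a single partition by one of
## four ensemble methods: majority voting, k-modes, CSPA and LCE.

#' Align one partition's cluster IDs to a reference partition
#'
#' Cluster IDs are arbitrary, so partitions must be aligned before voting.
#' The mapping maximising total contingency-table overlap is found by
#' solving the linear assignment problem on the `k1 x k2` contingency table
#' (zero-padded square when `k1 != k2`). Memberships are unchanged; only
#' the cluster IDs are renamed.
#'
#' @param labels integer partition to rename.
#' @param reference integer partition to align to (same length).
#' @return `labels` with renamed cluster IDs.
#' @export
#' @examples
#' relabelPartition(c(2, 2, 1, 1), c(1, 1, 2, 2))
relabelPartition <- function(labels, reference) {
  stopIfNot(length(labels) == length(reference), "labels and reference differ in length")
  k1 <- max(labels)
  k2 <- max(reference)
  k <- max(k1, k2)
  tab <- matrix(0, k, k)
  ct <- table(factor(labels, levels = seq_len(k)), factor(reference, levels = seq_len(k)))
  tab[] <- ct
  perm <- as.integer(clue::solve_LSAP(tab, maximum = TRUE))
  out <- perm[labels]
  names(out) <- names(labels)
  out
}

newSolution <- function(method, labels, k, degenerate = FALSE) {
  labels <- as.integer(labels)
  nonEmpty <- length(unique(labels))
  if (k >= 2 && nonEmpty < 2) degenerate <- TRUE
  new("EnsembleSolution",
    method = method, labels = labels, k = as.integer(k),
    degenerate = degenerate
  )
}

## shared degeneracy check for dendrogram cuts: the k-cluster partition is
## arbitrary when the k- and (k-1)-cluster solutions merge at the same height
cutWithFlag <- function(hc, k, n) {
  labels <- denseLabels(cutree(hc, k = k))
  h <- sort(hc$height)
  deg <- n > k && (h[n - k + 1] - h[n - k]) <= 1e-12
  list(labels = labels, degenerate = deg)
}

#' Majority-voting consensus
#'
#' Every run is aligned to a reference run with [relabelPartition()], then
#' each sample takes its modal label across runs (ties to the smallest
#' label).
#'
#' @param lm label matrix from [labelMatrix()] (samples x runs, entries in
#'   `1..k`).
#' @param k target cluster count (defaults to the matrix's `"k"` attribute,
#'   else the largest label).
#' @param reference column index of the run used as alignment reference.
#' @return an [EnsembleSolution-class].
#' @export
majorityVote <- function(lm, k = NULL, reference = 1L) {
  lm <- as.matrix(lm)
  if (is.null(k)) k <- attr(lm, "k") %||% max(lm)
  stopIfNot(reference >= 1 && reference <= ncol(lm), "reference run out of range")
  aligned <- vapply(
    seq_len(ncol(lm)),
    function(j) relabelPartition(lm[, j], lm[, reference]),
    integer(nrow(lm))
  )
  labels <- apply(aligned, 1, modalLabel)
  names(labels) <- rownames(lm)
  newSolution("majority_voting", labels, k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' K-modes consensus
#'
#' Treats each sample's vector of run labels as categorical data and
#' clusters samples by k-modes: simple-matching dissimilarity (number of
#' disagreeing positions), per-position-majority mode updates, initial
#' modes drawn (seeded) from `k` distinct rows. All ties break to the
#' smallest index. Final cluster IDs are renumbered by first occurrence.
#'
#' @param lm label matrix (samples x runs).
#' @param k target cluster count.
#' @param seed integer seed for the initial mode draws.
#' @param maxIter iteration cap per start, default 100.
#' @param nStart number of seeded initialisations; the solution with the
#'   lowest total simple-matching cost is kept (k-modes is sensitive to its
#'   starting modes).
#' @return an [EnsembleSolution-class].
#' @export
kmodesConsensus <- function(lm, k = NULL, seed = 1, maxIter = 100, nStart = 20) {
  lm <- as.matrix(lm)
  if (is.null(k)) k <- attr(lm, "k") %||% max(lm)
  n <- nrow(lm)
  rows <- apply(lm, 1, paste, collapse = ",")
  distinct <- which(!duplicated(rows))
  if (length(distinct) < k) {
    warning("fewer than k distinct label vectors; grouping identical rows")
    labels <- match(rows, rows[distinct])
    names(labels) <- rownames(lm)
    return(newSolution("kmodes", labels, k, degenerate = length(distinct) < 2 && k >= 2))
  }
  oneStart <- function(startSeed) {
    modes <- lm[withSeed(startSeed, sample(distinct, k)), , drop = FALSE]
    assign <- rep(0L, n)
    dmat <- NULL
    for (iter in seq_len(maxIter)) {
      dmat <- vapply(
        seq_len(k),
        function(c) rowSums(lm != matrix(modes[c, ], n, ncol(lm), byrow = TRUE)),
        numeric(n)
      )
      newAssign <- max.col(-dmat, ties.method = "first")
      if (identical(newAssign, assign)) break
      assign <- newAssign
      for (c in seq_len(k)) {
        members <- which(assign == c)
        if (!length(members)) next # empty cluster keeps its previous mode
        modes[c, ] <- apply(lm[members, , drop = FALSE], 2, modalLabel)
      }
    }
    list(assign = assign, cost = sum(dmat[cbind(seq_len(n), assign)]))
  }
  best <- NULL
  for (s in seq_len(nStart)) {
    cand <- oneStart(deriveSeed(seed, "kmodes_start", s))
    if (is.null(best) || cand$cost < best$cost) best <- cand
  }
  labels <- denseLabels(best$assign)
  names(labels) <- rownames(lm)
  newSolution("kmodes", labels, k)
}

#' Cluster-based similarity partitioning (CSPA) consensus
#'
#' Re-clusters the samples using the co-clustering proportions as a
#' similarity: average-linkage hierarchical clustering on `1 - consensus`,
#' cut at `k`. (The cut is flagged degenerate when the dendrogram offers no
#' separation at `k` clusters.)
#'
#' @param lm label matrix (samples x runs); used to compute the consensus
#'   matrix when `cm` is not supplied.
#' @param k target cluster count.
#' @param cm optional precomputed [ConsensusMatrix-class] for this slice.
#' @return an [EnsembleSolution-class].
#' @export
cspa <- function(lm, k = NULL, cm = NULL) {
  if (is.null(cm)) cm <- consensusMatrix(lm)
  if (is.null(k)) k <- attr(lm, "k") %||% max(lm)
  v <- cm@values
  n <- nrow(v)
  hc <- hclust(as.dist(1 - v), method = "average")
  cut <- cutWithFlag(hc, k, n)
  labels <- cut$labels
  names(labels) <- rownames(v)
  newSolution("CSPA", labels, k, degenerate = cut$degenerate)
}

#' Link-based cluster ensemble (LCE) consensus
#'
#' Builds the binary sample-by-cluster membership matrix over all clusters
#' of all runs; scores cluster-cluster similarity by shared membership
#' (Jaccard); refines it with the weighted connected-triples rule
#' (similarity transmitted through common neighbour clusters, normalised by
#' the largest triple weight); fills the sample-cluster association matrix
#' (1 for members, otherwise `dc` times the best refined similarity to any
#' cluster containing the sample); and partitions samples by
#' average-linkage hierarchical clustering of the association rows
#' (Euclidean), cut at `k`.
#'
#' @param lm label matrix (samples x runs).
#' @param k target cluster count.
#' @param dc decay constant in `[0, 1]` damping indirect associations,
#'   default 0.8. `dc = 0` reduces the association matrix to the binary
#'   membership matrix.
#' @return an [EnsembleSolution-class].
#' @export
lce <- function(lm, k = NULL, dc = 0.8) {
  stopIfNot(dc >= 0 && dc <= 1, "dc must be in [0, 1]")
  lm <- as.matrix(lm)
  if (is.null(k)) k <- attr(lm, "k") %||% max(lm)
  n <- nrow(lm)
  # binary membership over all clusters of all runs (empty clusters dropped)
  blocks <- lapply(seq_len(ncol(lm)), function(j) {
    labs <- sort(unique(lm[, j]))
    m <- matrix(0L, n, length(labs))
    m[cbind(seq_len(n), match(lm[, j], labs))] <- 1L
    m
  })
  M <- do.call(cbind, blocks)
  C <- ncol(M)
  sizes <- colSums(M)
  inter <- crossprod(M)
  union <- outer(sizes, sizes, "+") - inter
  S0 <- inter / union # Jaccard shared-membership similarity
  diag(S0) <- 1
  # weighted connected triples: WCT(c,d) = sum_q min(S0(c,q), S0(d,q)), q != c,d
  WCT <- matrix(0, C, C)
  for (q in seq_len(C)) {
    a <- S0[, q]
    WCT <- WCT + pmin(matrix(a, C, C), matrix(a, C, C, byrow = TRUE))
  }
  WCT <- WCT - 2 * pmin(S0, 1) # remove the q = c and q = d terms
  diag(WCT) <- 0
  wMax <- max(WCT)
  S <- if (wMax > 0) WCT / wMax else matrix(0, C, C)
  # refined association: member -> 1, else dc * best similarity to an own cluster
  R <- matrix(0, n, C)
  for (i in seq_len(n)) {
    own <- which(M[i, ] == 1L)
    best <- if (length(own) == 1L) S[, own] else apply(S[, own, drop = FALSE], 1, max)
    R[i, ] <- dc * best
    R[i, own] <- 1
  }
  hc <- hclust(dist(R), method = "average")
  cut <- cutWithFlag(hc, k, n)
  labels <- cut$labels
  names(labels) <- rownames(lm)
  newSolution("LCE", labels, k, degenerate = cut$degenerate)
}

#' The consensus methods of the ensemble
#'
#' @return character vector naming the four consensus-formation methods.
#' @export
consensusMethods <- function() {
  c("majority_voting", "kmodes", "CSPA", "LCE")
}

#' Run one named consensus method on a label matrix
#'
#' @param method one of [consensusMethods()].
#' @param lm label matrix (samples x runs).
#' @param k target cluster count.
#' @param seed seed (used by k-modes initialisation).
#' @param dc LCE decay constant.
#' @param cm optional precomputed consensus matrix (used by CSPA).
#' @return an [EnsembleSolution-class].
#' @export
runConsensus <- function(method, lm, k = NULL, seed = 1, dc = 0.8, cm = NULL) {
  stopIfNot(method %in% consensusMethods(),
    "unknown consensus method '", method, "'; available: ",
    paste(consensusMethods(), collapse = ", ")
  )
  switch(method,
    majority_voting = majorityVote(lm, k),
    kmodes = kmodesConsensus(lm, k, seed = seed),
    CSPA = cspa(lm, k, cm = cm),
    LCE = lce(lm, k, dc = dc)
  )
}
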