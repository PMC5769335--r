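# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive (loops, enumeration) and share no code with the package
# implementations they check.

# pairwise co-clustering proportions by explicit pair counting
bruteConsensusMatrix <- function(lm) {
  n <- nrow(lm)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      co <- 0
      joint <- 0
      for (r in seq_len(ncol(lm))) {
        if (!is.na(lm[i, r]) && !is.na(lm[j, r])) {
          joint <- joint + 1
          if (lm[i, r] == lm[j, r]) co <- co + 1
        }
      }
      out[i, j] <- if (joint > 0) co / joint else NA_real_
    }
  }
  diag(out) <- 1
  out
}

# PAC by direct open-interval counting on the upper triangle
brutePAC <- function(values, lower, upper) {
  inside <- 0
  total <- 0
  n <- nrow(values)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      v <- values[i, j]
      if (is.na(v)) next
      total <- total + 1
      if (v > lower && v < upper) inside <- inside + 1
    }
  }
  inside / total
}

# all permutations of 1..n as a matrix (one per row)
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1
  for (first in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      rest <- sub[r, ] + (sub[r, ] >= first) # remaining values, order by sub
      out[row, ] <- c(first, rest)
      row <- row + 1
    }
  }
  out
}

countPairsTogether <- function(a, b) {
  n <- length(a)
  cnt <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (a[i] == a[j] && b[i] == b[j]) cnt <- cnt + 1
    }
  }
  cnt
}

# ARI oracle: the permutation-model expectation computed by averaging the
# together-pair count over ALL reorderings of one partition
bruteARI <- function(labels, reference) {
  n <- length(labels)
  obs <- countPairsTogether(labels, reference)
  perms <- allPermutations(n)
  expCnt <- mean(apply(perms, 1, function(p) countPairsTogether(labels[p], reference)))
  choose2 <- function(v) sum(v * (v - 1) / 2)
  maxCnt <- (choose2(table(labels)) + choose2(table(reference))) / 2
  if (maxCnt == expCnt) return(1)
  (obs - expCnt) / (maxCnt - expCnt)
}

# best label mapping by exhaustive search over injections into padded IDs
bruteRelabelOverlap <- function(labels, reference) {
  k <- max(max(labels), max(reference))
  perms <- allPermutations(k)
  best <- -1
  for (p in seq_len(nrow(perms))) {
    best <- max(best, sum(perms[p, ][labels] == reference))
  }
  best
}

# exhaustive footrule-optimal ordering cost over all algorithm orderings
bruteFootruleCost <- function(ranks) {
  m <- nrow(ranks)
  perms <- allPermutations(m)
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    ordering <- rownames(ranks)[perms[r, ]]
    pos <- match(rownames(ranks), ordering)
    cost <- sum(abs(ranks - pos), na.rm = TRUE)
    best <- min(best, cost)
  }
  best
}

# mean silhouette width straight from its definition
bruteSilhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) {
      s[i] <- 0
      next
    }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(
      setdiff(unique(labels), labels[i]),
      function(c) mean(d[i, labels == c]), numeric(1)
    ))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# a tiny well-separated blob fixture shared across tests
blobFixture <- function(nPer = c(20, 20, 20), p = 5, sep = 10, seed = 1) {
  simulateMixture(nPer, nFeatures = p, centers = sep, clusterSd = 1, seed = seed)
}

# completed label matrix for one k of a small generated ensemble
smallLabelMatrix <- function(fx, k = 3, reps = 4, algorithms = c("kmeans", "pam", "hc_average"),
                             seed = 11) {
  ce <- suppressMessages(generateArray(fx$data,
    kValues = k,
    algorithms = builtinAlgorithms(algorithms), reps = reps, seed = seed
  ))
  labelMatrix(completeByKNN(ce), k)
}
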