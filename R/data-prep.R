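## data preparation: loading, sanitising, scaling/filtering, distances.
## The clustering substrate is a plain numeric matrix, rows = samples
## (rownames = sample IDs), columns = features.

supportedMetrics <- function() {
  c("euclidean", "manhattan", "spearman_dissimilarity", "pearson_dissimilarity")
}

#' Load a samples-by-features matrix from a delimited text file
#'
#' Reads a CSV/TSV table with rows as samples and columns as features. When
#' the first column is non-numeric it is taken as the sample IDs; a header
#' row supplies feature IDs.
#'
#' @param path path to the file.
#' @param delimiter field separator, default `","` (use `"\t"` for TSV).
#' @param header logical; does the first row name the features?
#' @return numeric matrix with unique rownames (sample IDs) and colnames.
#' @export
loadMatrix <- function(path, delimiter = ",", header = TRUE) {
  stopIfNot(file.exists(path), "file not found: ", path)
  raw <- tryCatch(
    read.table(path,
      sep = delimiter, header = header, stringsAsFactors = FALSE,
      check.names = FALSE, colClasses = NA
    ),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  stopIfNot(nrow(raw) >= 3, "need at least 3 samples, got ", nrow(raw))
  firstIsId <- !is.numeric(raw[[1]])
  ids <- if (firstIsId) as.character(raw[[1]]) else paste0("S", seq_len(nrow(raw)))
  vals <- if (firstIsId) raw[-1] else raw
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad)) {
    # report the first offending row for each non-numeric column
    col <- bad[1]
    suppressWarnings(conv <- as.numeric(as.character(vals[[col]])))
    row <- which(is.na(conv) & !is.na(vals[[col]]))[1]
    stop(sprintf(
      "non-numeric value in column '%s' at data row %s",
      names(vals)[col], ifelse(is.na(row), "?", row)
    ), call. = FALSE)
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  stopIfNot(!anyDuplicated(ids), "duplicated sample IDs in first column")
  rownames(m) <- ids
  if (is.null(colnames(m))) colnames(m) <- paste0("F", seq_len(ncol(m)))
  stopIfNot(!anyDuplicated(colnames(m)), "duplicated feature IDs in header")
  m
}

#' Prepare a data matrix for ensemble clustering
#'
#' Optional feature-wise standardisation (mean 0, population standard
#' deviation 1; constant features are dropped with a warning), selection of
#' the highest-variance features, and median imputation of missing cells.
#' Missing values are an error unless `imputeMissing = TRUE`. Scaling is off
#' by default: the pipeline is deliberately agnostic about what the features
#' measure.
#'
#' @param x numeric matrix, samples in rows.
#' @param scale standardise each feature to mean 0 and population sd 1?
#' @param topVarFeatures optional count: keep only this many highest-variance
#'   features (ties broken by original feature order).
#' @param imputeMissing replace missing cells by the feature median?
#' @return the prepared numeric matrix.
#' @export
#' @examples
#' x <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, dimnames = list(paste0("s", 1:3), c("a", "b")))
#' colMeans(prepareMatrix(x, scale = TRUE))
prepareMatrix <- function(x, scale = FALSE, topVarFeatures = NULL,
                          imputeMissing = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopIfNot(nrow(x) >= 3, "need at least 3 samples")
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  allMissing <- colSums(!is.na(x)) == 0
  stopIfNot(!any(allMissing), "feature(s) entirely missing: ",
    paste(colnames(x)[allMissing], collapse = ", ")
  )
  if (anyNA(x)) {
    stopIfNot(imputeMissing, "missing values present; set imputeMissing = TRUE to impute")
    for (j in which(colSums(is.na(x)) > 0)) {
      x[is.na(x[, j]), j] <- median(x[, j], na.rm = TRUE)
    }
  }
  if (!is.null(topVarFeatures)) {
    stopIfNot(
      topVarFeatures >= 1 && topVarFeatures <= ncol(x),
      "topVarFeatures must be between 1 and the number of features"
    )
    v <- apply(x, 2, var)
    keep <- order(-v)[seq_len(topVarFeatures)] # order() is stable: ties keep feature order
    x <- x[, sort(keep), drop = FALSE]
  }
  if (scale) {
    mu <- colMeans(x)
    sdPop <- sqrt(colMeans(sweep(x, 2, mu)^2))
    const <- sdPop == 0
    if (any(const)) {
      warning(
        "dropping constant feature(s): ",
        paste(colnames(x)[const], collapse = ", ")
      )
      x <- x[, !const, drop = FALSE]
      mu <- mu[!const]
      sdPop <- sdPop[!const]
    }
    x <- sweep(sweep(x, 2, mu), 2, sdPop, "/")
  }
  stopIfNot(ncol(x) >= 1, "no features survive preparation")
  x
}

#' Pairwise sample distances under a named metric
#'
#' Supports Euclidean and Manhattan distances and the correlation
#' dissimilarities `1 - cor` (Pearson or Spearman) computed across features.
#'
#' @param x prepared numeric matrix, samples in rows.
#' @param metric one of `"euclidean"`, `"manhattan"`,
#'   `"spearman_dissimilarity"`, `"pearson_dissimilarity"`.
#' @return symmetric numeric matrix of distances with a `"metric"` attribute.
#' @export
#' @examples
#' pairwiseDistance(rbind(a = c(0, 0), b = c(3, 4), c = c(0, 1)), "euclidean")["a", "b"]
pairwiseDistance <- function(x, metric = "euclidean") {
  stopIfNot(
    metric %in% supportedMetrics(),
    "unknown metric '", metric, "'; supported: ",
    paste(supportedMetrics(), collapse = ", ")
  )
  d <- switch(metric,
    euclidean = as.matrix(dist(x, method = "euclidean")),
    manhattan = as.matrix(dist(x, method = "manhattan")),
    pearson_dissimilarity = 1 - cor(t(x), method = "pearson"),
    spearman_dissimilarity = 1 - cor(t(x), method = "spearman")
  )
  # correlation dissimilarities: guard tiny negative values from rounding
  d[d < 0 & d > -1e-12] <- 0
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  attr(d, "metric") <- metric
  d
}
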