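## Persisting results and simple diagnostics plots. Numeric columns are
## written with 10 significant digits so outputs are byte-stable across
## runs and platforms.

fmtNum <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

#' Write ensemble solutions as CSV
#'
#' One row per (sample, method): `sample_id, method, k, label`.
#'
#' @param solutions list of [EnsembleSolution-class] objects.
#' @param path output CSV path.
#' @param sampleIds sample identifiers (recycled across methods).
#' @return `path`, invisibly.
#' @export
writeSolutions <- function(solutions, path, sampleIds = NULL) {
  rows <- lapply(solutions, function(sol) {
    ids <- sampleIds %||% names(clusterLabels(sol)) %||%
      paste0("S", seq_along(clusterLabels(sol)))
    data.frame(
      sample_id = ids, method = sol@method, k = sol@k,
      label = clusterLabels(sol), stringsAsFactors = FALSE
    )
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist a full pipeline result to a directory
#'
#' Writes `labels.csv` (final solutions), `consensus_k<k>.csv` (dense
#' consensus matrices), `validity.csv`, `ranking.csv`, `weights.csv` (when
#' weighting is on), `significance.csv` (when tests ran), `summary.json`
#' (selected k, PAC and delta-AUC per k, ranking, weights, p-values) and
#' `config.yaml` (the configuration echo).
#'
#' @param result a [DiceResult-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDiceResult <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeSolutions(result@solutions, file.path(dir, "labels.csv"))
  for (k in names(result@consensusMatrices)) {
    v <- consensusValues(result@consensusMatrices[[k]])
    out <- cbind(
      data.frame(sample_id = rownames(v) %||% paste0("S", seq_len(nrow(v)))),
      as.data.frame(apply(v, 2, fmtNum))
    )
    write.csv(out, file.path(dir, paste0("consensus_k", k, ".csv")),
      row.names = FALSE, quote = FALSE
    )
  }
  val <- result@validity
  val$score <- fmtNum(val$score)
  write.csv(val, file.path(dir, "validity.csv"), row.names = FALSE, quote = FALSE)
  write.csv(
    data.frame(rank = seq_along(result@ranking), algorithm = result@ranking),
    file.path(dir, "ranking.csv"),
    row.names = FALSE, quote = FALSE
  )
  if (length(result@weights)) {
    write.csv(
      data.frame(
        algorithm = names(result@weights),
        weight = fmtNum(result@weights)
      ),
      file.path(dir, "weights.csv"),
      row.names = FALSE, quote = FALSE
    )
  }
  if (nrow(result@significance)) {
    sig <- result@significance
    sig$observed_ci <- fmtNum(sig$observed_ci)
    sig$p_value <- fmtNum(sig$p_value)
    write.csv(sig, file.path(dir, "significance.csv"), row.names = FALSE, quote = FALSE)
  }
  summary <- list(
    selected_k = result@selectedK,
    pac = as.list(result@pac),
    delta_auc = as.list(result@deltaAUC),
    ranking = result@ranking,
    weights = as.list(result@weights),
    significance = if (nrow(result@significance)) result@significance else NULL,
    config = result@config[!vapply(result@config, is.null, logical(1))]
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE
  )
  yaml::write_yaml(
    result@config[!vapply(result@config, is.null, logical(1))],
    file.path(dir, "config.yaml")
  )
  invisible(dir)
}

#' Plot consensus CDFs across cluster sizes
#'
#' @param cdfs named list from [consensusCDF()] (names = k).
#' @return invisibly, `NULL`; draws on the current device.
#' @export
plotCDF <- function(cdfs) {
  graphics::plot(NULL,
    xlim = c(0, 1), ylim = c(0, 1),
    xlab = "consensus value", ylab = "CDF", main = "Consensus CDFs"
  )
  cols <- seq_along(cdfs)
  for (i in cols) {
    graphics::lines(cdfs[[i]], col = i, do.points = FALSE, verticals = TRUE)
  }
  graphics::legend("bottomright",
    legend = paste0("k=", names(cdfs)),
    col = cols, lty = 1, bty = "n"
  )
  invisible(NULL)
}

#' Plot the per-k change in CDF area
#'
#' @param dAUC named numeric from [deltaAUC()].
#' @return invisibly, `NULL`.
#' @export
plotDeltaAUC <- function(dAUC) {
  graphics::plot(as.integer(names(dAUC)), dAUC,
    type = "b",
    xlab = "k", ylab = "relative change in CDF area", main = "Delta AUC"
  )
  invisible(NULL)
}

#' Cluster-sorted consensus-matrix heatmap
#'
#' @param cm a [ConsensusMatrix-class].
#' @param labels optional partition used to order the samples.
#' @return invisibly, `NULL`.
#' @export
consensusHeatmap <- function(cm, labels = NULL) {
  v <- consensusValues(cm)
  ord <- if (is.null(labels)) {
    hclust(as.dist(1 - v), method = "average")$order
  } else {
    order(labels)
  }
  graphics::image(v[ord, rev(ord)],
    axes = FALSE, main = "Consensus matrix",
    col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE)
  )
  invisible(NULL)
}
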