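#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats dist hclust cutree kmeans cor cov median mad var sd
#'   rnorm as.dist as.hclust ecdf setNames
#' @importFrom utils read.table write.csv head modifyList
#' @importFrom mclust Mclust mclustBIC
NULL

## Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
## caller's .Random.seed afterwards so library calls never perturb user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Derive a reproducible 32-bit seed from a base seed and run coordinates
#'
#' Each (repetition, algorithm, k) run of the generation step gets its own
#' RNG stream so runs are independent yet reproducible, and so inserting or
#' removing an algorithm does not shift the seeds of the others. The
#' derivation is a plain FNV-1a-style string hash folded to a positive
#' 31-bit integer.
#'
#' @param seed Integer base seed.
#' @param ... Further coordinates (numbers or strings) identifying the run.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' deriveSeed(42, 1, "kmeans", 3)
deriveSeed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "\r")
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- (h %% 2^24) * 16777619 + (h %/% 2^24) * 16777619 %% 2^32 + b
    h <- h %% 2^32
  }
  as.integer(h %% .Machine$integer.max)
}

## Modal value of an integer vector; ties broken by the smallest label.
modalLabel <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_integer_)
  tab <- tabulate(x)
  which.max(tab) # which.max returns the first (= smallest label) maximum
}

## Relabel an integer partition to 1..k by order of first occurrence.
denseLabels <- function(labels) {
  u <- unique(labels[!is.na(labels)])
  out <- match(labels, u)
  as.integer(out)
}

stopIfNot <- function(cond, ...) {
  if (!cond) stop(..., call. = FALSE)
}
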