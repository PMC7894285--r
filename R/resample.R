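## One-tailed gene-set resampling tests (Monte Carlo permutation nulls).

#' Per-gene expression values from a normalized matrix
#'
#' Summarizes each gene across samples before any gene-set statistic is
#' taken: the median (default) or mean of normalized counts across the
#' replicate columns. For a plain named vector the values are returned
#' as-is.
#'
#' @param x A \link[SummarizedExperiment]{SummarizedExperiment} carrying a
#'   \code{"normalized"} assay, a numeric matrix of normalized values, or a
#'   named numeric vector of per-gene values.
#' @param gene_summary Cross-sample summary: \code{"median"} or
#'   \code{"mean"}.
#' @return Named numeric vector, one value per gene.
#' @export
geneLevelValues <- function(x, gene_summary = c("median", "mean")) {
  gene_summary <- match.arg(gene_summary)
  if (methods::is(x, "SummarizedExperiment")) {
    if (!"normalized" %in% SummarizedExperiment::assayNames(x))
      stop("no 'normalized' assay; run normalizeCounts() first")
    x <- assay(x, "normalized")
  }
  if (is.matrix(x) || methods::is(x, "Matrix")) {
    m <- as.matrix(x)
    v <- if (gene_summary == "median") matrixStats::rowMedians(m)
         else rowMeans(m)
    return(stats::setNames(v, rownames(m)))
  }
  if (is.numeric(x)) {
    if (is.null(names(x))) stop("per-gene vector must be named by gene id")
    return(x)
  }
  stop("unsupported input for per-gene values")
}

#' Summary statistic of a gene set
#'
#' @inheritParams geneLevelValues
#' @param genes Nonempty character vector of gene ids present in \code{x}.
#' @param statistic \code{"median"} or \code{"mean"} over the set's
#'   per-gene values.
#' @return A single number.
#' @export
summaryExpression <- function(x, genes, statistic = c("median", "mean"),
                              gene_summary = "median") {
  statistic <- match.arg(statistic)
  vals <- geneLevelValues(x, gene_summary)
  if (length(genes) == 0L) stop("empty gene set")
  missing <- setdiff(genes, names(vals))
  if (length(missing))
    stop("genes absent from matrix: ", paste(head(missing, 5), collapse = ", "))
  v <- vals[genes]
  if (statistic == "median") stats::median(v) else mean(v)
}

# Core Monte Carlo engine on a named per-gene value vector. Draws n_perm
# gene sets of the focal size from `pool` without replacement within each
# draw, recomputes the statistic, and applies the add-one estimator. Ties
# count toward the tail (>= / <=), which is conservative.
resampleCore <- function(values, focal, pool, n_perm, seed, statistic,
                         alternative) {
  if (length(focal) == 0L) stop("empty focal gene set")
  if (length(pool) < length(focal))
    stop("pool (", length(pool), ") smaller than focal (", length(focal), ")")
  missing <- setdiff(c(focal, pool), names(values))
  if (length(missing))
    stop("genes without values: ", paste(head(missing, 5), collapse = ", "))
  n_perm <- assertCount(n_perm, "n_perm", allow_zero = FALSE)
  stat_fun <- if (statistic == "median") matrixStats::colMedians else
    base::colMeans
  obs <- if (statistic == "median") stats::median(values[focal])
         else mean(values[focal])
  pv <- unname(values[pool])
  m <- length(focal)
  null <- withSeed(seed, {
    idx <- vapply(seq_len(n_perm),
                  function(i) sample.int(length(pv), m),
                  integer(m))
    stat_fun(matrix(pv[idx], nrow = m))
  })
  tail_hits <- if (alternative == "high") sum(null >= obs) else
    sum(null <= obs)
  p <- (1 + tail_hits) / (1 + n_perm)
  new("ResampleResult", observed = obs,
      nullQuantiles = stats::quantile(null, c(0.025, 0.25, 0.5, 0.75, 0.975)),
      p = p, nPerm = n_perm, seed = as.integer(seed),
      focalSize = length(focal), poolSize = length(pool),
      statistic = statistic, alternative = alternative)
}

#' Resampling test of a gene set's summary expression
#'
#' Tests whether the focal set's summary statistic (median by default) is
#' high (or low) relative to repeated size-matched random gene draws from a
#' pool. Two pool conventions are in use and the caller chooses by what it
#' passes: for "category versus control category" contrasts the pool is the
#' control set only; for "category versus all genes in its pathways" the
#' pool includes the focal genes. When \code{focal} equals \code{pool} every
#' draw reproduces the observed set and p = 1.
#'
#' @inheritParams summaryExpression
#' @param focal Character vector of focal gene ids.
#' @param pool Character vector of pool gene ids to resample from.
#' @param n_perm Number of Monte Carlo draws (default 10000).
#' @param seed Integer seed; identical seeds give identical draws.
#' @param alternative \code{"high"} (default) or \code{"low"}.
#' @return A \linkS4class{ResampleResult}.
#' @export
resampleMedianTest <- function(x, focal, pool, n_perm = 10000L, seed = 1L,
                               statistic = c("median", "mean"),
                               alternative = c("high", "low"),
                               gene_summary = "median") {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  values <- geneLevelValues(x, gene_summary)
  resampleCore(values, focal, pool, n_perm, seed, statistic, alternative)
}

#' @describeIn resampleMedianTest Printer.
#' @param object A \linkS4class{ResampleResult}.
#' @export
setMethod("show", "ResampleResult", function(object) {
  cat(sprintf(
    "ResampleResult: observed %s = %.4g (focal %d vs pool %d, tail '%s')\n",
    object@statistic, object@observed, object@focalSize, object@poolSize,
    object@alternative))
  cat(sprintf("  one-tailed p = %.4g  (n_perm = %d, seed = %d)\n",
              object@p, object@nPerm, object@seed))
})

#' Extract the p-value of a ResampleResult
#'
#' @param x A \linkS4class{ResampleResult}.
#' @return The one-tailed Monte Carlo p-value.
#' @export
pValue <- function(x) x@p
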