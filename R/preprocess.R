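## Single-cell QC, median-of-ratios normalization, pseudobulk aggregation.

#' QC thresholds for single-cell filtering
#'
#' Defaults implement the two-stage filter used for the tooth single-cell
#' data: a basic pass keeping cells with >= 20 detected genes and genes
#' detected in >= 3 cells, then a robust-cell pass keeping cells with
#' detected genes in \[3000, 9000\] (inclusive), UMI totals in
#' \[7000, 180000\] (inclusive) and mitochondrial fraction strictly below
#' 0.10. Range inclusivity follows the plain reading of "from ... to" and
#' "<"; all bounds are configurable.
#'
#' @param min_genes_per_cell Minimum detected genes per cell (inclusive).
#' @param min_cells_per_gene Minimum expressing cells per gene (inclusive).
#' @param robust_gene_range Inclusive detected-gene window for robust cells.
#' @param robust_umi_range Inclusive UMI-total window for robust cells.
#' @param max_mito_fraction Exclusive upper bound on mitochondrial fraction.
#' @return A validated list of thresholds.
#' @export
qcThresholds <- function(min_genes_per_cell = 20L,
                         min_cells_per_gene = 3L,
                         robust_gene_range = c(3000L, 9000L),
                         robust_umi_range = c(7000L, 180000L),
                         max_mito_fraction = 0.10) {
  if (length(robust_gene_range) != 2L || diff(robust_gene_range) < 0 ||
      length(robust_umi_range) != 2L || diff(robust_umi_range) < 0)
    stop("ranges must be ordered pairs")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must lie in [0, 1]")
  if (min_genes_per_cell < 0 || min_cells_per_gene < 0)
    stop("minimum thresholds must be non-negative")
  list(min_genes_per_cell = as.integer(min_genes_per_cell),
       min_cells_per_gene = as.integer(min_cells_per_gene),
       robust_gene_range = as.integer(robust_gene_range),
       robust_umi_range = as.numeric(robust_umi_range),
       max_mito_fraction = max_mito_fraction)
}

newQCReport <- function(removed, kept, stages) {
  new("QCReport", removed = removed, kept = kept, stages = stages)
}

#' @describeIn qcThresholds Printer for QC reports.
#' @param object A \linkS4class{QCReport}.
#' @export
setMethod("show", "QCReport", function(object) {
  cat("QCReport (stages: ", paste(object@stages, collapse = " -> "), ")\n",
      sep = "")
  for (nm in names(object@removed))
    cat("  removed ", object@removed[[nm]], " by ", nm, "\n", sep = "")
  cat("  kept: ", object@kept[["cells"]], " cells, ",
      object@kept[["genes"]], " genes\n", sep = "")
})

#' Basic cell/gene detection filter
#'
#' Applies the cell filter (>= \code{min_genes_per_cell} detected genes)
#' then the gene filter (detected in >= \code{min_cells_per_gene} of the
#' retained cells), in that order, once (no iteration to a fixpoint,
#' matching the single-pass behavior of standard toolkits).
#'
#' @param sce A \link[SingleCellExperiment]{SingleCellExperiment}.
#' @param thresholds From [qcThresholds()].
#' @return List with the filtered \code{sce} and a \linkS4class{QCReport}.
#' @export
basicFilter <- function(sce, thresholds = qcThresholds()) {
  cnt <- assay(sce, "counts")
  keep_cells <- Matrix::colSums(cnt > 0) >= thresholds$min_genes_per_cell
  cnt2 <- cnt[, keep_cells, drop = FALSE]
  keep_genes <- Matrix::rowSums(cnt2 > 0) >= thresholds$min_cells_per_gene
  out <- refreshCellStats(sce[keep_genes, keep_cells])
  S4Vectors::metadata(out)$qc_stages <-
    c(S4Vectors::metadata(sce)$qc_stages, "basic")
  report <- newQCReport(
    removed = c(cells_min_genes = sum(!keep_cells),
                genes_min_cells = sum(!keep_genes)),
    kept = c(cells = ncol(out), genes = nrow(out)),
    stages = S4Vectors::metadata(out)$qc_stages)
  list(sce = out, report = report)
}

#' Mitochondrial fraction of a cell
#'
#' @param sce A \link[SingleCellExperiment]{SingleCellExperiment} with
#'   \code{rowData()$mito}.
#' @param cell_id Single cell barcode/name, or omitted for all cells.
#' @return Fraction(s) in \[0, 1\]: mito-flagged counts over total counts.
#'   Zero-total cells raise an error for a single requested cell.
#' @export
mitoFraction <- function(sce, cell_id = NULL) {
  cnt <- assay(sce, "counts")
  mito <- rowData(sce)$mito
  tot <- Matrix::colSums(cnt)
  mt <- if (any(mito)) Matrix::colSums(cnt[mito, , drop = FALSE])
        else numeric(ncol(cnt))
  if (!is.null(cell_id)) {
    if (!cell_id %in% colnames(cnt)) stop("unknown cell: ", cell_id)
    if (tot[[cell_id]] == 0)
      stop("cell ", cell_id, " has zero total counts; fraction undefined")
    return(unname(mt[[cell_id]] / tot[[cell_id]]))
  }
  frac <- ifelse(tot > 0, mt / tot, NA_real_)
  stats::setNames(frac, colnames(cnt))
}

#' Robust-cell filter (gene window, UMI window, mitochondrial cap)
#'
#' Keeps cells whose detected-gene count lies in the inclusive
#' \code{robust_gene_range}, whose UMI total lies in the inclusive
#' \code{robust_umi_range}, and whose mitochondrial fraction is strictly
#' below \code{max_mito_fraction}. Expects [basicFilter()] to have run
#' first (tracked via the QC lineage; a warning is emitted otherwise).
#'
#' @inheritParams basicFilter
#' @return List with the filtered \code{sce} and a \linkS4class{QCReport}
#'   reporting removals per rule (a cell failing several rules is counted
#'   under each).
#' @export
robustCellFilter <- function(sce, thresholds = qcThresholds()) {
  if (!"basic" %in% S4Vectors::metadata(sce)$qc_stages)
    warning("robustCellFilter applied without a preceding basicFilter")
  ng <- colData(sce)$nGenes
  numi <- colData(sce)$nUMI
  mf <- mitoFraction(sce)
  ok_genes <- ng >= thresholds$robust_gene_range[1] &
              ng <= thresholds$robust_gene_range[2]
  ok_umi <- numi >= thresholds$robust_umi_range[1] &
            numi <= thresholds$robust_umi_range[2]
  ok_mito <- !is.na(mf) & mf < thresholds$max_mito_fraction
  keep <- ok_genes & ok_umi & ok_mito
  out <- refreshCellStats(sce[, keep])
  S4Vectors::metadata(out)$qc_stages <-
    c(S4Vectors::metadata(sce)$qc_stages, "robust")
  report <- newQCReport(
    removed = c(cells_gene_range = sum(!ok_genes),
                cells_umi_range = sum(!ok_umi),
                cells_mito = sum(!ok_mito),
                cells_total = sum(!keep)),
    kept = c(cells = ncol(out), genes = nrow(out)),
    stages = S4Vectors::metadata(out)$qc_stages)
  list(sce = out, report = report)
}

#' Median-of-ratios size factors
#'
#' Classic estimator: the reference pseudo-sample is the per-gene geometric
#' mean across columns, restricted to genes with nonzero counts in every
#' column; each column's factor is the median over those genes of
#' count / reference.
#'
#' @param counts genes x samples (or genes x cells, or a mixed pseudobulk +
#'   bulk) matrix of non-negative counts; >= 2 columns.
#' @return Named numeric vector of positive size factors, with the
#'   reference-gene ids in attribute \code{"reference_genes"}.
#' @export
medianRatioSizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least two samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has nonzero counts in all samples; consider pooling ",
         "cells to pseudobulk before normalizing")
  ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(col)
    stats::median(col / ref))
  if (any(sf <= 0)) stop("non-positive size factor computed")
  structure(sf, reference_genes = rownames(counts)[pos])
}

#' Normalize counts by size factors
#'
#' Divides each column by its size factor. No gene-length scaling is
#' applied anywhere in the package.
#'
#' @param x A matrix, \link[SummarizedExperiment]{SummarizedExperiment}, or
#'   \link[SingleCellExperiment]{SingleCellExperiment} with assay
#'   \code{"counts"}.
#' @param size_factors Positive numeric vector, one per column. For
#'   containers, computed with [medianRatioSizeFactors()] when omitted.
#' @return Same shape as the input counts: a numeric matrix (sparse stays
#'   sparse); for containers, the input object with a new assay
#'   \code{"normalized"}.
#' @export
normalizeCounts <- function(x, size_factors = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    cnt <- assay(x, "counts")
    if (is.null(size_factors))
      size_factors <- medianRatioSizeFactors(as.matrix(cnt))
    SummarizedExperiment::assay(x, "normalized") <-
      normalizeCounts(cnt, size_factors)
    return(x)
  }
  if (length(size_factors) != ncol(x))
    stop("need one size factor per column")
  assertPositive(size_factors, "size factors")
  if (methods::is(x, "sparseMatrix")) {
    out <- x %*% Matrix::Diagonal(x = 1 / size_factors, names = FALSE)
    dimnames(out) <- dimnames(x)
    out
  } else {
    sweep(x, 2, size_factors, "/")
  }
}

#' Sum single cells to pseudobulk
#'
#' Sums raw counts over cells within each group; the result is treated as a
#' bulk library. Total mass is conserved exactly.
#'
#' @param sce A \link[SingleCellExperiment]{SingleCellExperiment}.
#' @param grouping Factor/character of length \code{ncol(sce)} assigning
#'   every cell to a sample; no \code{NA}s.
#' @param species,stage Metadata for the resulting bulk samples.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} of integer
#'   sums, one column per group.
#' @export
pseudobulkSum <- function(sce, grouping, species = "mouse", stage = "E14") {
  if (length(grouping) != ncol(sce) || anyNA(grouping))
    stop("every cell must be assigned to a group")
  grouping <- factor(grouping)
  cnt <- assay(sce, "counts")
  ind <- Matrix::sparseMatrix(i = seq_along(grouping),
                              j = as.integer(grouping),
                              x = 1,
                              dims = c(length(grouping), nlevels(grouping)))
  agg <- as.matrix(cnt %*% ind)
  colnames(agg) <- levels(grouping)
  storage.mode(agg) <- "integer"
  makeBulkExperiment(agg, species = species, stage = stage,
                     replicate = seq_len(ncol(agg)))
}
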