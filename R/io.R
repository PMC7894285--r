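## Container constructors and plain-text readers/writers.
##
## Bulk matrices travel as TSV (gene_id + one column per sample); single-cell
## matrices as the MatrixMarket trio (matrix.mtx, genes.tsv, barcodes.tsv)
## with a mito flag column in genes.tsv.

#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom SummarizedExperiment "assay<-" "colData<-" assayNames
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

#' Build a bulk SummarizedExperiment from an integer count matrix
#'
#' @param counts genes x samples matrix of non-negative integers with
#'   rownames (gene ids).
#' @param species,stage Sample metadata, recycled across samples.
#' @param replicate Replicate labels; defaults to 1..n.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{"counts"}.
#' @export
makeBulkExperiment <- function(counts, species = "mouse", stage = "E14",
                               replicate = seq_len(ncol(counts))) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene-id rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("bulk counts must be non-negative integers")
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("%s_%s_rep%d", species, stage, replicate)
  SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(species = rep_len(species, ncol(counts)),
                        stage = rep_len(stage, ncol(counts)),
                        replicate = rep_len(replicate, ncol(counts)),
                        row.names = colnames(counts)))
}

#' Build a single-cell SingleCellExperiment from a sparse count matrix
#'
#' Per-cell totals (\code{nUMI}) and detected-gene counts (\code{nGenes})
#' are computed from the matrix and cached in \code{colData()}; they always
#' equal the column sums/nonzero counts of the assay.
#'
#' @param counts genes x cells sparse (or dense) matrix of non-negative
#'   integers with dimnames.
#' @param mito Logical per-gene mitochondrial flag, aligned to rows.
#' @return A \link[SingleCellExperiment]{SingleCellExperiment} with assay
#'   \code{"counts"} and \code{rowData()$mito}.
#' @export
makeCellExperiment <- function(counts, mito = rep(FALSE, nrow(counts))) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts))) stop("counts must have gene-id rownames")
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  if (length(mito) != nrow(counts))
    stop("mito flags must align with genes")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("cell counts must be non-negative integers")
  sce <- SingleCellExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(gene_id = rownames(counts), mito = as.logical(mito),
                        row.names = rownames(counts)))
  refreshCellStats(sce)
}

# Recompute the cached per-cell totals; called after any subsetting.
refreshCellStats <- function(sce) {
  cnt <- assay(sce, "counts")
  colData(sce)$nUMI <- Matrix::colSums(cnt)
  colData(sce)$nGenes <- Matrix::colSums(cnt > 0)
  sce
}

#' Read and write bulk count TSVs
#'
#' Format: header \code{gene_id} then one column per sample; integer counts;
#' \code{#} comment lines ignored.
#'
#' @param se A bulk \link[SummarizedExperiment]{SummarizedExperiment}.
#' @param path TSV path.
#' @param species,stage Metadata applied on read.
#' @return \code{writeBulkCounts} returns \code{path} invisibly;
#'   \code{readBulkCounts} returns a SummarizedExperiment.
#' @export
writeBulkCounts <- function(se, path) {
  df <- data.frame(gene_id = rownames(se),
                   as.data.frame(assay(se, "counts")),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBulkCounts
#' @export
readBulkCounts <- function(path, species = "mouse", stage = "E14") {
  if (!file.exists(path)) stop("bulk count file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (colnames(df)[1] != "gene_id")
    stop("bulk TSV must start with a gene_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  makeBulkExperiment(m, species = species, stage = stage)
}

#' Read and write the MatrixMarket trio for single-cell counts
#'
#' \code{writeCellCounts} writes \code{matrix.mtx} (1-based coordinate
#' MatrixMarket), \code{genes.tsv} (columns gene_id, symbol, mito as 0/1)
#' and \code{barcodes.tsv} into \code{dir}. \code{readCellCounts} inverts it
#' bit-exactly at the count level.
#'
#' @param sce A \link[SingleCellExperiment]{SingleCellExperiment}.
#' @param dir Directory (created if needed).
#' @return \code{writeCellCounts} returns \code{dir} invisibly;
#'   \code{readCellCounts} returns a SingleCellExperiment.
#' @export
writeCellCounts <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cnt <- assay(sce, "counts")
  Matrix::writeMM(cnt, file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(gene_id = rownames(sce), symbol = rownames(sce),
               mito = as.integer(rowData(sce)$mito)),
    file.path(dir, "genes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname writeCellCounts
#' @export
readCellCounts <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  if (!all(file.exists(paths)))
    stop("expected matrix.mtx, genes.tsv, barcodes.tsv under ", dir)
  m <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
  genes <- utils::read.delim(paths[2], colClasses = "character")
  barcodes <- readLines(paths[3])
  if (nrow(genes) != nrow(m) || length(barcodes) != ncol(m))
    stop("genes/barcodes do not match matrix dimensions")
  dimnames(m) <- list(genes$gene_id, barcodes)
  makeCellExperiment(m, mito = genes$mito == "1")
}
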