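## Cell-level transcript abundance, expression-domain decomposition, and the
## category / pathway / molecule-type comparisons built on the resampling
## engine.

normalizedCellMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    if (!"normalized" %in% SummarizedExperiment::assayNames(x))
      stop("no 'normalized' assay; run normalizeCounts() first")
    x <- assay(x, "normalized")
  }
  if (!(is.matrix(x) || methods::is(x, "Matrix")))
    stop("expected a normalized genes x cells matrix")
  if (is.null(rownames(x))) stop("matrix must have gene-id rownames")
  x
}

#' Cell-level transcript abundance
#'
#' For each gene, the expression-domain size \code{n} is the number of
#' cells with nonzero normalized expression, and the cell-level abundance
#' \code{x_bar} is the mean normalized expression over those \code{n}
#' cells only. The organ-level total is then exactly
#' \code{total = x_bar * n}. Genes expressed in no cell have \code{n = 0}
#' and an undefined (NA) \code{x_bar}, flagged by \code{defined = FALSE}.
#'
#' @param x Normalized genes x cells matrix, or a
#'   \link[SingleCellExperiment]{SingleCellExperiment} with a
#'   \code{"normalized"} assay.
#' @param genes Optional subset of gene ids; unknown ids raise an error.
#' @param min_expr Expression threshold defining "expressing": cells with
#'   values strictly greater than \code{min_expr} count toward the domain.
#'   The default 0 implements the nonzero-reads reading; set 1 for the
#'   stricter variant.
#' @return A \linkS4class{DataFrame} with columns \code{gene_id}, \code{n},
#'   \code{x_bar}, \code{total}, \code{defined}.
#' @export
cellLevelAbundance <- function(x, genes = NULL, min_expr = 0) {
  m <- normalizedCellMatrix(x)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing))
      stop("unknown gene(s): ", paste(head(missing, 5), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  expressed <- m > min_expr
  n <- as.numeric(Matrix::rowSums(expressed))
  total <- as.numeric(Matrix::rowSums(m * expressed))
  x_bar <- ifelse(n > 0, total / n, NA_real_)
  DataFrame(gene_id = rownames(m), n = n, x_bar = x_bar,
            total = x_bar * n, defined = n > 0, row.names = rownames(m))
}

#' Decompose organ-level expression into domain size and abundance
#'
#' Computes the per-gene profile (\code{n}, \code{x_bar},
#' \code{total = n * x_bar}) and the Spearman rank correlation between the
#' organ-level total and the expression-domain size, quantifying how much
#' of organ-level expression is driven by how many cells express a gene
#' rather than how strongly each expressing cell does.
#'
#' @inheritParams cellLevelAbundance
#' @return List with \code{profile} (the [cellLevelAbundance()] DataFrame)
#'   and \code{spearman} (correlation of \code{total} and \code{n} over
#'   genes with \code{n > 0}).
#' @export
domainDecomposition <- function(x, genes = NULL, min_expr = 0) {
  prof <- cellLevelAbundance(x, genes, min_expr)
  ok <- prof$defined
  rho <- if (sum(ok) >= 3)
    stats::cor(prof$total[ok], prof$n[ok], method = "spearman")
  else NA_real_
  list(profile = prof, spearman = rho)
}

#' Compare cell-level abundance between two gene categories
#'
#' Computes per-gene cell-level abundance \code{x_bar} for the focal and
#' reference category genes (restricted to genes expressed in at least one
#' cell), then tests whether the focal category's summary is high by
#' drawing size-matched gene sets from the combined focal-plus-reference
#' pool (a gene-level label permutation). With
#' \code{include_focal = FALSE} the null draws come from the reference
#' category only, the convention for category-versus-control contrasts; in
#' that mode a focal set exceeding every reference gene attains the minimum
#' p of \code{1/(n_perm + 1)}.
#'
#' @inheritParams cellLevelAbundance
#' @param table A \linkS4class{CategoryTable}.
#' @param focal_category,reference_category Category tokens.
#' @param n_perm,seed,statistic As in [resampleMedianTest()].
#' @param include_focal Include focal genes in the sampling pool (label
#'   permutation; default) or resample from the reference genes only.
#' @return A \linkS4class{ResampleResult}.
#' @export
abundanceCategoryTest <- function(x, table, focal_category,
                                  reference_category, n_perm = 10000L,
                                  seed = 1L, statistic = c("median", "mean"),
                                  min_expr = 0, include_focal = TRUE) {
  statistic <- match.arg(statistic)
  m <- normalizedCellMatrix(x)
  focal <- intersect(categoryGenes(table, focal_category), rownames(m))
  ref <- intersect(categoryGenes(table, reference_category), rownames(m))
  prof <- cellLevelAbundance(m, union(focal, ref), min_expr)
  defined <- prof$gene_id[prof$defined]
  focal <- intersect(focal, defined)
  ref <- intersect(ref, defined)
  if (length(focal) == 0L || length(ref) == 0L)
    stop("a category is empty after restricting to expressed genes")
  vals <- stats::setNames(prof$x_bar, prof$gene_id)[defined]
  pool <- if (include_focal) union(focal, ref) else setdiff(ref, focal)
  resampleCore(vals, focal, pool, n_perm, seed, statistic,
               alternative = "high")
}

#' Test a category's expression within its signaling-pathway context
#'
#' The pool is the union of the genes annotated to the requested pathways
#' (plus any focal-category genes measured in the matrix, so the focal set
#' is always part of its own context); the focal set is the category's
#' genes. With \code{exclude_ligands = TRUE} ligand-type genes are removed
#' from both focal set and pool before testing, isolating the contribution
#' of non-secreted gene products.
#'
#' @inheritParams resampleMedianTest
#' @param table A \linkS4class{CategoryTable}.
#' @param focal_category Category token.
#' @param pathways Pathway tokens defining the context pool.
#' @param exclude_ligands Drop ligand-type genes from focal and pool.
#' @return A \linkS4class{ResampleResult}.
#' @export
pathwayContextTest <- function(x, table, focal_category,
                               pathways = allPathways(),
                               exclude_ligands = FALSE, n_perm = 10000L,
                               seed = 1L, statistic = c("median", "mean"),
                               gene_summary = "median") {
  statistic <- match.arg(statistic)
  values <- geneLevelValues(x, gene_summary)
  focal <- intersect(categoryGenes(table, focal_category), names(values))
  pool <- union(intersect(pathwayGeneSet(table, pathways), names(values)),
                focal)
  if (exclude_ligands) {
    lig <- names(moleculeTypes(table))[moleculeTypes(table) == "ligand"]
    focal <- setdiff(focal, lig)
    pool <- setdiff(pool, lig)
  }
  if (length(pool) == 0L)
    stop("pathway pool empty", if (exclude_ligands) " after ligand exclusion")
  if (length(focal) == 0L)
    stop("focal category empty", if (exclude_ligands) " after ligand exclusion")
  resampleCore(values, focal, pool, n_perm, seed, statistic,
               alternative = "high")
}

#' Expression-domain size by molecule type, with a ligands-low test
#'
#' Summarizes per-gene expression-domain sizes (\code{n}, the number of
#' expressing cells) by molecule type within a gene scope — either the
#' keystone progression + shape category genes or all pathway-annotated
#' genes — and tests the one-tailed hypothesis that ligand domains are
#' small, by resampling size-matched sets from the genes of all the other
#' molecule types (default), or from the whole scope including the ligands
#' when \code{include_focal = TRUE} (the conditionally exact
#' label-permutation form; the other-types-only null is slightly
#' anti-conservative when ligands are a large share of the scope).
#'
#' @inheritParams cellLevelAbundance
#' @param table A \linkS4class{CategoryTable}.
#' @param gene_scope \code{"category_genes"} (progression + shape) or
#'   \code{"pathway_genes"} (all six-pathway genes).
#' @param n_perm,seed,statistic As in [resampleMedianTest()].
#' @param include_focal Include the ligand genes themselves in the null
#'   draws.
#' @return List with \code{summaries} (per molecule type: gene count,
#'   median and mean domain size) and \code{result} (the ligands-low
#'   \linkS4class{ResampleResult}).
#' @export
domainSizeByMoleculeType <- function(x, table,
                                     gene_scope = c("category_genes",
                                                    "pathway_genes"),
                                     n_perm = 10000L, seed = 1L,
                                     statistic = c("median", "mean"),
                                     min_expr = 0, include_focal = FALSE) {
  gene_scope <- match.arg(gene_scope)
  statistic <- match.arg(statistic)
  m <- normalizedCellMatrix(x)
  scope <- if (gene_scope == "category_genes")
    c(categoryGenes(table, "progression"), categoryGenes(table, "shape"))
  else pathwayGeneSet(table, allPathways())
  scope <- intersect(scope, rownames(m))
  if (length(scope) == 0L) stop("no scope genes measured in the matrix")
  prof <- cellLevelAbundance(m, scope, min_expr)
  types <- moleculeTypes(table)[scope]
  summaries <- do.call(rbind, lapply(split(prof$n, types), function(nn)
    data.frame(n_genes = length(nn), median_n = stats::median(nn),
               mean_n = mean(nn))))
  summaries <- DataFrame(molecule_type = rownames(summaries), summaries)
  lig <- scope[types == "ligand"]
  other <- scope[types != "ligand"]
  if (length(lig) == 0L) stop("no ligand-type genes in scope")
  vals <- stats::setNames(prof$n, prof$gene_id)
  pool <- if (include_focal) scope else other
  res <- resampleCore(vals, lig, pool, n_perm, seed, statistic,
                      alternative = "low")
  list(summaries = summaries, result = res)
}
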