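#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

## Controlled vocabularies ---------------------------------------------------

#' Controlled vocabularies for gene annotation
#'
#' Category labels encode the phenotypic severity of a null mutation in the
#' developing tooth: \code{progression} (development arrests), \code{shape}
#' (morphology altered), \code{tissue} (enamel/dentine defects),
#' \code{dispensable} (no detectable single-knockout tooth phenotype),
#' \code{double} (phenotype only in combined mutants),
#' \code{developmental_process} (GO-style developmental pool used as a
#' control), and \code{other} (remaining protein-coding genes).
#'
#' @return A character vector of valid tokens.
#' @examples
#' keystoneCategories()
#' @export
keystoneCategories <- function() {
  c("progression", "shape", "tissue", "dispensable", "double")
}

#' @rdname keystoneCategories
#' @export
allCategories <- function() {
  c(keystoneCategories(), "developmental_process", "other")
}

#' @rdname keystoneCategories
#' @export
allPathways <- function() {
  c("Wnt", "Tgfb", "Fgf", "Hh", "Eda", "Notch")
}

#' @rdname keystoneCategories
#' @export
allMoleculeTypes <- function() {
  c("ligand", "receptor", "intracellular", "transcription_factor",
    "other", "unannotated")
}

## CategoryTable -------------------------------------------------------------

#' CategoryTable: phenotype-severity gene classification
#'
#' Holds one record per gene with its severity category, signaling-pathway
#' membership (a gene may belong to several of the six pathways), inferred
#' molecule type, and an optional flag marking membership in the
#' developmental-process control pool. The five keystone categories are
#' mutually exclusive by construction (each gene carries exactly one primary
#' category label and duplicated gene ids are rejected).
#'
#' @slot records A \linkS4class{DataFrame} with columns \code{gene_id},
#'   \code{symbol}, \code{category}, \code{pathways} (comma-joined string,
#'   possibly empty), \code{molecule_type}, \code{dev_process} (logical).
#' @slot species Species tag, e.g. \code{"mouse"}.
#'
#' @seealso [loadCategoryTable()], [countByCategory()], [pathwayGeneSet()]
#' @export
setClass("CategoryTable",
  slots = c(records = "DataFrame", species = "character"))

setValidity("CategoryTable", function(object) {
  rec <- object@records
  need <- c("gene_id", "symbol", "category", "pathways", "molecule_type",
            "dev_process")
  if (!all(need %in% colnames(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  if (any(!nzchar(rec$gene_id)))
    msgs <- c(msgs, "empty gene_id")
  dup <- unique(rec$gene_id[duplicated(rec$gene_id)])
  if (length(dup))
    msgs <- c(msgs, paste0("duplicate gene_id (possible category-exclusivity ",
      "violation): ", paste(head(dup, 10), collapse = ", ")))
  bad <- setdiff(unique(rec$category), allCategories())
  if (length(bad))
    msgs <- c(msgs, paste("unknown category token:", paste(bad, collapse = ", ")))
  badm <- setdiff(unique(rec$molecule_type), allMoleculeTypes())
  if (length(badm))
    msgs <- c(msgs, paste("unknown molecule_type token:",
                          paste(badm, collapse = ", ")))
  pw <- setdiff(unlist(strsplit(rec$pathways[nzchar(rec$pathways)], ",")),
                allPathways())
  if (length(pw))
    msgs <- c(msgs, paste("unknown pathway token:", paste(pw, collapse = ", ")))
  if (length(object@species) != 1L)
    msgs <- c(msgs, "species must be a single string")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

## QCReport ------------------------------------------------------------------

#' QCReport: removed-entity bookkeeping for single-cell filters
#'
#' @slot removed Named integer vector: rule -> number of removed entities.
#' @slot kept Named integer vector with \code{cells} and \code{genes} retained.
#' @slot stages Character vector of filter stages applied, in order.
#' @export
setClass("QCReport",
  slots = c(removed = "integer", kept = "integer", stages = "character"))

## ResampleResult ------------------------------------------------------------

#' ResampleResult: outcome of a one-tailed gene-set resampling test
#'
#' The null distribution is built by repeatedly drawing gene sets of the
#' focal size from a pool (without replacement within each draw) and
#' recomputing the summary statistic. The Monte Carlo p-value uses the
#' add-one estimator \eqn{p = (1 + \#\{null \ge obs\}) / (1 + n_{perm})}
#' (\eqn{\le} for the "low" alternative), so the attainable minimum is
#' \eqn{1/(n_{perm}+1)} and p is never exactly zero.
#'
#' @slot observed Observed focal-set summary statistic.
#' @slot nullQuantiles Named numeric: quantiles of the resampled null.
#' @slot p One-tailed Monte Carlo p-value.
#' @slot nPerm Number of resampling draws.
#' @slot seed Seed used for the draws.
#' @slot focalSize,poolSize Sizes of the focal set and the sampling pool.
#' @slot statistic Summary statistic name ("median" or "mean").
#' @slot alternative Tail direction: "high" (focal elevated) or "low".
#' @export
setClass("ResampleResult",
  slots = c(observed = "numeric", nullQuantiles = "numeric", p = "numeric",
            nPerm = "integer", seed = "integer", focalSize = "integer",
            poolSize = "integer", statistic = "character",
            alternative = "character"))

setValidity("ResampleResult", function(object) {
  if (object@p < 1 / (object@nPerm + 1) - 1e-12 || object@p > 1 + 1e-12)
    return("p outside [1/(nPerm+1), 1]")
  if (!object@statistic %in% c("median", "mean"))
    return("statistic must be 'median' or 'mean'")
  if (!object@alternative %in% c("high", "low"))
    return("alternative must be 'high' or 'low'")
  TRUE
})
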