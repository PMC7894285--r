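## Construction and IO for the phenotype-severity gene classification.

#' Construct a CategoryTable from vectors
#'
#' @param gene_id Character vector of unique, nonempty gene identifiers.
#' @param category Character vector of category labels (see
#'   [allCategories()]).
#' @param symbol Display symbols; defaults to \code{gene_id}.
#' @param pathways Character vector of comma-joined pathway memberships
#'   (subset of [allPathways()]); \code{""} for none.
#' @param molecule_type Molecule-type labels; missing values become
#'   \code{"unannotated"}.
#' @param dev_process Logical flag: gene belongs to the developmental-process
#'   control pool. Defaults to \code{category == "developmental_process"}.
#' @param species Species tag.
#'
#' @return A validated \linkS4class{CategoryTable}.
#' @examples
#' ct <- CategoryTable(gene_id = c("g1", "g2"),
#'                     category = c("progression", "dispensable"))
#' countByCategory(ct)
#' @export
CategoryTable <- function(gene_id, category, symbol = gene_id,
                          pathways = "", molecule_type = "unannotated",
                          dev_process = NULL, species = "mouse") {
  n <- length(gene_id)
  molecule_type[is.na(molecule_type) | !nzchar(molecule_type)] <- "unannotated"
  pathways[is.na(pathways)] <- ""
  if (is.null(dev_process))
    dev_process <- category == "developmental_process"
  rec <- DataFrame(gene_id = as.character(gene_id),
                   symbol = rep_len(as.character(symbol), n),
                   category = rep_len(as.character(category), n),
                   pathways = rep_len(as.character(pathways), n),
                   molecule_type = rep_len(as.character(molecule_type), n),
                   dev_process = rep_len(as.logical(dev_process), n))
  new("CategoryTable", records = rec, species = species)
}

#' Load a gene category table from TSV
#'
#' Expects a UTF-8 TSV with header columns \code{gene_id}, \code{symbol},
#' \code{category}, \code{pathways} (comma-joined within the field),
#' \code{molecule_type}; lines starting with \code{#} are ignored. An
#' optional \code{dev_process} column (0/1) marks membership in the
#' developmental-process control pool for keystone genes that also carry a
#' GO developmental annotation.
#'
#' @param path Path to the TSV file.
#' @param species Species tag recorded in the table.
#' @return A validated \linkS4class{CategoryTable}. Rows violating the
#'   controlled vocabularies, or duplicated gene ids (which would break the
#'   mutual exclusivity of the keystone categories), raise an error naming
#'   the offending tokens.
#' @export
loadCategoryTable <- function(path, species = "mouse") {
  if (!file.exists(path)) stop("category table not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character",
                          check.names = FALSE)
  need <- c("gene_id", "symbol", "category", "pathways", "molecule_type")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("category table missing columns: ", paste(missing, collapse = ", "))
  dev <- if ("dev_process" %in% colnames(df))
    df$dev_process %in% c("1", "TRUE", "true") else NULL
  CategoryTable(gene_id = df$gene_id, symbol = df$symbol,
                category = df$category, pathways = df$pathways,
                molecule_type = df$molecule_type, dev_process = dev,
                species = species)
}

#' Write a CategoryTable to TSV
#'
#' @param table A \linkS4class{CategoryTable}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCategoryTable <- function(table, path) {
  df <- as.data.frame(table@records)
  df$dev_process <- as.integer(df$dev_process)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Accessors -----------------------------------------------------------------

#' Accessors for CategoryTable
#'
#' @param x,object A \linkS4class{CategoryTable}.
#' @return \code{geneIds} returns the gene identifiers; \code{categories}
#'   the per-gene category labels (named by gene id); \code{moleculeTypes}
#'   the per-gene molecule types; \code{speciesTag} the species string;
#'   \code{nGenes} the record count.
#' @name CategoryTable-accessors
NULL

#' @rdname CategoryTable-accessors
#' @export
geneIds <- function(x) x@records$gene_id

#' @rdname CategoryTable-accessors
#' @export
categories <- function(x) {
  stats::setNames(x@records$category, x@records$gene_id)
}

#' @rdname CategoryTable-accessors
#' @export
moleculeTypes <- function(x) {
  stats::setNames(x@records$molecule_type, x@records$gene_id)
}

#' @rdname CategoryTable-accessors
#' @export
speciesTag <- function(x) x@species

#' @rdname CategoryTable-accessors
#' @export
nGenes <- function(x) nrow(x@records)

#' @rdname CategoryTable-accessors
#' @export
setMethod("show", "CategoryTable", function(object) {
  cnt <- countByCategory(object)
  cat("CategoryTable [", object@species, "] with ", nrow(object@records),
      " genes\n", sep = "")
  cat("  ", paste(names(cnt), cnt, sep = ":", collapse = "  "), "\n", sep = "")
})

## Queries -------------------------------------------------------------------

#' Count genes per category
#'
#' @param table A \linkS4class{CategoryTable}.
#' @return Named integer vector over all category tokens (zero for absent
#'   categories); the counts sum to the number of records.
#' @export
countByCategory <- function(table) {
  tab <- table(factor(table@records$category, levels = allCategories()))
  stats::setNames(as.integer(tab), names(tab))
}

#' Gene ids of one category
#'
#' @param table A \linkS4class{CategoryTable}.
#' @param category A single category token.
#' @return Character vector of gene ids.
#' @export
categoryGenes <- function(table, category) {
  category <- match.arg(category, allCategories())
  table@records$gene_id[table@records$category == category]
}

#' Developmental-process control pool
#'
#' Returns the genes flagged as belonging to the developmental-process pool.
#' Genes carrying a keystone category label are reported under that label in
#' keystone analyses; they enter this pool only when
#' \code{include_keystone_overlap = TRUE}, making the overlap handling
#' explicit.
#'
#' @param table A \linkS4class{CategoryTable}.
#' @param include_keystone_overlap Include keystone-labelled genes whose
#'   \code{dev_process} flag is set.
#' @return Character vector of gene ids.
#' @export
developmentalProcessPool <- function(table, include_keystone_overlap = FALSE) {
  rec <- table@records
  sel <- rec$dev_process
  if (!include_keystone_overlap)
    sel <- sel & !(rec$category %in% keystoneCategories())
  rec$gene_id[sel]
}

#' Fraction of a category with a given molecule type
#'
#' E.g. the fraction of shape-category genes that are secreted ligands.
#'
#' @param table A \linkS4class{CategoryTable}.
#' @param category A single category token; must contain at least one gene.
#' @param molecule_type A single molecule-type token.
#' @return Fraction in \[0, 1\] (raw, not rounded). Use
#'   \code{round(x, 2)}-style display rounding downstream.
#' @export
moleculeTypeFraction <- function(table, category, molecule_type) {
  category <- match.arg(category, allCategories())
  molecule_type <- match.arg(molecule_type, allMoleculeTypes())
  rec <- table@records
  incat <- rec$category == category
  if (!any(incat))
    stop("category '", category, "' has no genes; fraction undefined")
  sum(rec$molecule_type[incat] == molecule_type) / sum(incat)
}

#' Union of genes annotated to a set of pathways
#'
#' @param table A \linkS4class{CategoryTable}.
#' @param pathways Nonempty character vector of pathway tokens (subset of
#'   [allPathways()]).
#' @return Character vector of gene ids annotated to any requested pathway
#'   (deduplicated union; a gene in several pathways appears once).
#' @export
pathwayGeneSet <- function(table, pathways) {
  if (length(pathways) == 0L) stop("at least one pathway must be requested")
  bad <- setdiff(pathways, allPathways())
  if (length(bad)) stop("unknown pathway token: ", paste(bad, collapse = ", "))
  rec <- table@records
  memb <- strsplit(rec$pathways, ",", fixed = TRUE)
  hit <- vapply(memb, function(p) any(p %in% pathways), logical(1))
  unique(rec$gene_id[hit])
}

## Ortholog transfer ---------------------------------------------------------

#' Load a one-to-one ortholog map from TSV
#'
#' @param path TSV with columns \code{source_gene_id}, \code{target_gene_id}.
#' @return A data.frame validated to be strictly one-to-one.
#' @export
loadOrthologMap <- function(path) {
  if (!file.exists(path)) stop("ortholog map not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character")
  need <- c("source_gene_id", "target_gene_id")
  if (!all(need %in% colnames(df)))
    stop("ortholog map must have columns: ", paste(need, collapse = ", "))
  validateOrthologMap(df)
  df[, need]
}

validateOrthologMap <- function(map) {
  if (anyDuplicated(map$source_gene_id) || anyDuplicated(map$target_gene_id))
    stop("ortholog map is not one-to-one: duplicated source or target ids")
  invisible(map)
}

#' Transfer category annotations across species via one-to-one orthologs
#'
#' Keeps exactly the source genes present in the map, relabels them to the
#' target identifiers, and preserves all annotations. Genes without a
#' one-to-one ortholog are dropped; the number dropped is reported in a
#' message.
#'
#' @param table A \linkS4class{CategoryTable}.
#' @param map One-to-one map as from [loadOrthologMap()] (data.frame with
#'   \code{source_gene_id}, \code{target_gene_id}).
#' @param target_species Species tag for the returned table.
#' @return A \linkS4class{CategoryTable} for the target species.
#' @export
transferOrthologs <- function(table, map, target_species) {
  validateOrthologMap(map)
  rec <- table@records
  idx <- match(rec$gene_id, map$source_gene_id)
  keep <- !is.na(idx)
  dropped <- sum(!keep)
  if (dropped == nrow(rec) || nrow(rec) == 0L)
    warning("no genes mapped; returning empty table")
  message(dropped, " of ", nrow(rec),
          " genes had no one-to-one ortholog and were dropped")
  out <- rec[keep, , drop = FALSE]
  out$gene_id <- map$target_gene_id[idx[keep]]
  new("CategoryTable", records = out, species = target_species)
}
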