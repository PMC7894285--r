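## End-to-end orchestration: simulate/load -> QC -> normalize -> tests ->
## machine-readable report.

#' Per-cell normalization for abundance statistics
#'
#' Divides each cell by a library-size factor scaled to geometric mean 1
#' (each cell's UMI total over the geometric-mean total), the degenerate
#' form of the median-of-ratios estimator when no gene is detected in every
#' cell, and stores the result as the \code{"normalized"} assay. Organ-level
#' comparisons instead use [pseudobulkSum()] plus [medianRatioSizeFactors()]
#' jointly with bulk samples.
#'
#' @param sce A \link[SingleCellExperiment]{SingleCellExperiment}.
#' @return The object with a \code{"normalized"} assay added.
#' @export
normalizeCells <- function(sce) {
  tot <- colData(sce)$nUMI
  if (any(tot == 0)) stop("zero-total cells present; filter first")
  sf <- tot / exp(mean(log(tot)))
  SummarizedExperiment::assay(sce, "normalized") <-
    normalizeCounts(assay(sce, "counts"), sf)
  sce
}

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed for every stochastic stage.
#' @param n_perm Resampling draws per test.
#' @return Nested configuration list understood by [runPipeline()];
#'   equivalent YAML (see the package vignette) can be passed as a file
#'   path instead.
#' @export
defaultRunConfig <- function(out_dir = tempfile("keystone_run_"), seed = 1L,
                             n_perm = 10000L) {
  list(
    seed = seed,
    n_perm = n_perm,
    statistic = "median",
    out_dir = out_dir,
    simulate = list(
      category_counts = as.list(defaultCategoryCounts()),
      n_samples = 7L,
      n_cells = 400L,
      n_teeth = 4L
    ),
    qc = list(min_genes_per_cell = 20L, min_cells_per_gene = 3L,
              robust_gene_range = c(3000L, 9000L),
              robust_umi_range = c(7000L, 180000L),
              max_mito_fraction = 0.10),
    contrasts = list(
      list(name = "progression_vs_dispensable_bulk", type = "bulk_category",
           focal = "progression", reference = "dispensable"),
      list(name = "shape_vs_dispensable_bulk", type = "bulk_category",
           focal = "shape", reference = "dispensable"),
      list(name = "progression_abundance", type = "abundance",
           focal = "progression", reference = "dispensable"),
      list(name = "progression_in_pathways", type = "pathway_context",
           focal = "progression",
           pathways = c("Wnt", "Tgfb", "Fgf", "Hh")),
      list(name = "shape_in_pathways_no_ligands", type = "pathway_context",
           focal = "shape", pathways = allPathways(),
           exclude_ligands = TRUE),
      list(name = "ligand_domain_size", type = "domain_size",
           scope = "pathway_genes")
    )
  )
}

loadRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  base <- defaultRunConfig()
  merged <- utils::modifyList(base, config)
  # these are wholesale replacements, not key-by-key merges
  if (!is.null(config$contrasts)) merged$contrasts <- config$contrasts
  if (!is.null(config$simulate$category_counts))
    merged$simulate$category_counts <- config$simulate$category_counts
  if (is.null(merged$seed)) stop("config must set a seed")
  merged
}

validateContrasts <- function(contrasts, table) {
  present <- names(which(countByCategory(table) > 0))
  for (ct in contrasts) {
    for (fld in c("focal", "reference"))
      if (!is.null(ct[[fld]]) && !ct[[fld]] %in% present)
        stop("contrast '", ct$name, "': category '", ct[[fld]],
             "' absent from the category table")
    if (!is.null(ct$pathways)) {
      bad <- setdiff(ct$pathways, allPathways())
      if (length(bad))
        stop("contrast '", ct$name, "': unknown pathway ",
             paste(bad, collapse = ", "))
    }
  }
  invisible(contrasts)
}

resultAsList <- function(r) {
  list(observed = r@observed, p = r@p, n_perm = r@nPerm, seed = r@seed,
       focal_size = r@focalSize, pool_size = r@poolSize,
       statistic = r@statistic, alternative = r@alternative,
       null_quantiles = as.list(r@nullQuantiles))
}

#' Run the full analysis pipeline
#'
#' Stages, in fixed order: obtain inputs (simulate with the configured
#' preset, or load \code{config$inputs$category_table},
#' \code{config$inputs$bulk_tsv}, \code{config$inputs$cell_dir}); basic and
#' robust single-cell QC; normalization (median-of-ratios for bulk and for
#' pseudobulk jointly with bulk; per-cell library-size factors for
#' abundance); the configured contrasts; report. Contrasts are validated
#' against the category table before any computation. All stochastic
#' stages derive their streams from the single configured seed, so
#' re-running an identical config reproduces every number.
#'
#' @param config A configuration list as from [defaultRunConfig()], or a
#'   path to an equivalent YAML file.
#' @return The run report (invisibly also written to
#'   \code{out_dir/report.json}): per-contrast results, QC reports,
#'   category counts, molecule-type fractions, and provenance (config
#'   hash, package version, seed).
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  config <- loadRunConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  ## stage: inputs
  stage <- "inputs"
  report <- tryCatch({
    if (!is.null(config$inputs)) {
      table <- loadCategoryTable(config$inputs$category_table)
      bulk <- readBulkCounts(config$inputs$bulk_tsv)
      sce <- readCellCounts(config$inputs$cell_dir)
    } else {
      counts <- unlist(config$simulate$category_counts)
      table <- simulateCategoryTable(counts, seed = seed)
      bulk <- simulateBulkCounts(
        bulkSimParams(n_samples = config$simulate$n_samples), table,
        seed = deriveSeed(seed, 11L))$se
      sce <- simulateCellCounts(
        cellSimParams(n_cells = config$simulate$n_cells), table,
        seed = deriveSeed(seed, 12L))$sce
    }
    validateContrasts(config$contrasts, table)

    ## stage: qc
    stage <- "qc"
    thr <- do.call(qcThresholds, config$qc)
    bf <- basicFilter(sce, thr)
    rf <- robustCellFilter(bf$sce, thr)
    cells <- rf$sce
    if (ncol(cells) == 0L) stop("no cells survive the robust filter")

    ## stage: normalize
    stage <- "normalize"
    n_teeth <- config$simulate$n_teeth %||% 4L
    tooth <- rep_len(sprintf("tooth%d", seq_len(n_teeth)), ncol(cells))
    pb <- pseudobulkSum(cells, tooth)
    joint <- cbind(assay(bulk, "counts")[rownames(pb), , drop = FALSE],
                   assay(pb, "counts"))
    joint_sf <- medianRatioSizeFactors(joint)
    bulk_norm <- normalizeCounts(
      bulk, joint_sf[seq_len(ncol(bulk))])
    cells <- normalizeCells(cells)

    ## stage: stats
    stage <- "stats"
    contrasts <- lapply(config$contrasts, function(ct) {
      cseed <- deriveSeed(seed, 100L + digestSeed(ct$name))
      res <- switch(ct$type,
        bulk_category = resampleMedianTest(
          bulk_norm,
          focal = intersect(categoryGenes(table, ct$focal), rownames(bulk_norm)),
          pool = intersect(categoryGenes(table, ct$reference), rownames(bulk_norm)),
          n_perm = config$n_perm, seed = cseed,
          statistic = config$statistic),
        abundance = abundanceCategoryTest(
          cells, table, ct$focal, ct$reference,
          n_perm = config$n_perm, seed = cseed,
          statistic = config$statistic),
        pathway_context = pathwayContextTest(
          bulk_norm, table, ct$focal, ct$pathways,
          exclude_ligands = isTRUE(ct$exclude_ligands),
          n_perm = config$n_perm, seed = cseed,
          statistic = config$statistic),
        domain_size = domainSizeByMoleculeType(
          cells, table, gene_scope = ct$scope %||% "pathway_genes",
          n_perm = config$n_perm, seed = cseed,
          statistic = config$statistic)$result,
        stop("unknown contrast type: ", ct$type))
      c(list(name = ct$name, type = ct$type), resultAsList(res))
    })

    ## stage: report
    stage <- "report"
    mt_frac <- tryCatch(
      list(progression_ligand =
             moleculeTypeFraction(table, "progression", "ligand"),
           shape_ligand = moleculeTypeFraction(table, "shape", "ligand")),
      error = function(e) list())
    cfg_hash <- digest::digest(config[setdiff(names(config), "out_dir")])
    rep <- list(
      provenance = list(package = "keystoneExpr",
                        version = as.character(utils::packageVersion("keystoneExpr")),
                        seed = seed, config_hash = cfg_hash),
      category_counts = as.list(countByCategory(table)),
      molecule_type_fractions = mt_frac,
      qc = list(basic = as.list(bf$report@removed),
                robust = as.list(rf$report@removed),
                kept = as.list(rf$report@kept)),
      size_factors = as.list(joint_sf),
      contrasts = contrasts)
    ## per-gene tables for renderTables
    vals <- geneLevelValues(bulk_norm)
    attr(rep, "gene_values") <- data.frame(
      gene_id = names(vals), value = unname(vals),
      category = unname(categories(table)[names(vals)]))
    attr(rep, "profile") <- as.data.frame(cellLevelAbundance(cells))
    rep
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  renderTables(report, config$out_dir)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable small integer from a contrast name, for per-contrast seed streams.
digestSeed <- function(name) {
  sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 10000L
}

#' Render per-category summary tables from a run report
#'
#' Writes box-plot-style distribution summaries (first quartile, median,
#' mean, third quartile; type-7 quantiles) of per-gene expression values by
#' category, the per-gene abundance profile, and a per-contrast result
#' table.
#'
#' @param report A report from [runPipeline()].
#' @param out_dir Directory for TSV artifacts.
#' @return Named list of the data frames written.
#' @export
renderTables <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gv <- attr(report, "gene_values")
  out <- list()
  if (!is.null(gv)) {
    sp <- split(gv$value, gv$category)
    out$category_summary <- data.frame(
      category = names(sp),
      n = vapply(sp, length, integer(1)),
      q1 = vapply(sp, function(v) unname(stats::quantile(v, 0.25, type = 7)),
                  numeric(1)),
      median = vapply(sp, stats::median, numeric(1)),
      mean = vapply(sp, mean, numeric(1)),
      q3 = vapply(sp, function(v) unname(stats::quantile(v, 0.75, type = 7)),
                  numeric(1)))
    utils::write.table(out$category_summary,
                       file.path(out_dir, "category_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  prof <- attr(report, "profile")
  if (!is.null(prof)) {
    out$abundance_profile <- prof
    utils::write.table(prof, file.path(out_dir, "abundance_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cr <- report$contrasts
  out$contrast_results <- if (length(cr)) data.frame(
    name = vapply(cr, `[[`, character(1), "name"),
    type = vapply(cr, `[[`, character(1), "type"),
    observed = vapply(cr, `[[`, numeric(1), "observed"),
    p = vapply(cr, `[[`, numeric(1), "p"),
    n_perm = vapply(cr, function(x) as.integer(x$n_perm), integer(1)),
    focal_size = vapply(cr, function(x) as.integer(x$focal_size), integer(1)),
    pool_size = vapply(cr, function(x) as.integer(x$pool_size), integer(1)))
  else data.frame(name = character(), type = character(),
                  observed = numeric(), p = numeric(), n_perm = integer(),
                  focal_size = integer(), pool_size = integer())
  utils::write.table(out$contrast_results,
                     file.path(out_dir, "contrast_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
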