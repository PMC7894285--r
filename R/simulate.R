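## Synthetic bulk and single-cell count generators.
##
## Both arms use the negative binomial as the count model, the standard
## overdispersed choice for RNA counts. Gene baselines are lognormal.
## Single-cell expression separates two signals deliberately: domain
## membership (which cells express a gene at all; i.i.d. Bernoulli across
## cells) and conditional abundance (NB counts given expression), so that
## expression-domain size and per-cell abundance can be moved independently.

#' Default category composition for simulated gene tables
#'
#' The five keystone categories use the tabulated study sizes
#' (15/28/27/100/11). The developmental-process and other pools default to
#' 2000 and 10000 genes, a desk-scale gene universe large enough that
#' simulated cells detect thousands of genes.
#'
#' @return Named integer vector of gene counts per category.
#' @export
defaultCategoryCounts <- function() {
  c(progression = 15L, shape = 28L, tissue = 27L, dispensable = 100L,
    double = 11L, developmental_process = 2000L, other = 10000L)
}

# Default molecule-type sampling probabilities per category. Ligand
# fractions for progression (0.20) and shape (0.36) follow the study's
# tabulation; remaining mass is spread over the other types.
moleculeTypeProbs <- function(category) {
  lig <- switch(category, progression = 0.20, shape = 0.36, double = 0.25,
                tissue = 0.05, 0.12)
  rest <- 1 - lig
  c(ligand = lig, receptor = rest * 0.25, intracellular = rest * 0.40,
    transcription_factor = rest * 0.25, other = rest * 0.10)
}

# Probability that a gene of a category is annotated to a signaling pathway.
pathwayProb <- function(category) {
  switch(category, progression = 0.85, shape = 0.85, double = 0.6,
         tissue = 0.1, dispensable = 0.1, developmental_process = 0.08,
         other = 0.01)
}

#' Simulate a category table
#'
#' Generates synthetic gene ids with categories in the requested numbers.
#' Molecule types are sampled with category-specific probabilities (ligand
#' probability 0.20 for progression and 0.36 for shape, mirroring the
#' tabulated fractions); progression/shape genes are annotated to one of
#' the six pathways with high probability, control categories rarely.
#'
#' @param counts Named vector of non-negative gene counts per category
#'   (names from [allCategories()]).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param species Species tag.
#' @return A \linkS4class{CategoryTable}.
#' @examples
#' ct <- simulateCategoryTable(c(progression = 15, dispensable = 100), seed = 1)
#' countByCategory(ct)
#' @export
simulateCategoryTable <- function(counts = defaultCategoryCounts(), seed = 1,
                                  species = "synthetic-mouse") {
  bad <- setdiff(names(counts), allCategories())
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("negative counts requested")
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0L)
    return(CategoryTable(gene_id = character(), category = character(),
                         species = species))
  cats <- rep(names(counts), counts)
  withSeed(deriveSeed(seed, 1L), {
    ids <- sprintf("G%06d", seq_len(n))
    mt <- vapply(cats, function(cc) {
      p <- moleculeTypeProbs(cc)
      sample(names(p), 1L, prob = p)
    }, character(1))
    pw <- vapply(cats, function(cc) {
      if (stats::runif(1) < pathwayProb(cc)) {
        k <- if (stats::runif(1) < 0.08) 2L else 1L
        paste(sample(allPathways(), k), collapse = ",")
      } else ""
    }, character(1))
    # keystone genes may additionally carry the GO-style developmental flag
    dev <- cats == "developmental_process" |
      (cats %in% keystoneCategories() & stats::runif(n) < 0.8)
    CategoryTable(gene_id = ids, symbol = ids, category = cats,
                  pathways = pw, molecule_type = mt, dev_process = dev,
                  species = species)
  })
}

#' Simulation parameter bundles
#'
#' \code{bulkSimParams()} parameterizes the bulk generator: per-group sample
#' number (7, matching the mouse replicate design; rat arms use 5),
#' lognormal gene baselines, multiplicative per-category fold elevation,
#' NB dispersion, and expected library size. \code{cellSimParams()}
#' parameterizes the single-cell generator: per-category expression-domain
#' fractions, per-category conditional abundance multipliers, a ligand
#' domain-size multiplier (default 0.5: ligands occupy roughly half-sized
#' domains), lognormal per-cell depths, and mitochondrial content including
#' a small "damaged" cell fraction with elevated mitochondrial share to
#' exercise the <10% filter.
#'
#' @param n_samples Samples per group (bulk).
#' @param baseline_log_mean,baseline_log_sd Lognormal gene-baseline
#'   parameters (natural-log scale).
#' @param category_fold Named multiplicative elevation per category;
#'   unlisted categories default to 1.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param depth_per_sample Expected bulk library size.
#' @param depth_log_sd Lognormal spread of per-sample depths.
#' @param n_cells Number of cells.
#' @param domain_fraction Named per-category fraction of cells expressing a
#'   gene, in (0, 1]; or a per-gene numeric vector.
#' @param domain_jitter_sd Per-gene logit-scale jitter of domain fractions.
#' @param abundance_scale Named per-category multiplier of conditional
#'   per-cell abundance; or a per-gene vector.
#' @param ligand_domain_multiplier Multiplier applied to the domain fraction
#'   of ligand-type genes.
#' @param mito_gene_fraction Fraction of genes flagged mitochondrial.
#' @param mito_expression_share Target expected mitochondrial share of
#'   per-cell UMIs in healthy cells.
#' @param damaged_cell_fraction Fraction of cells with elevated
#'   mitochondrial share.
#' @param damaged_mito_share Expected mitochondrial share in damaged cells.
#' @param depth_log_mean Natural log of the typical per-cell UMI total.
#' @return A named list of validated parameters.
#' @export
bulkSimParams <- function(n_samples = 7L,
                          baseline_log_mean = log(200),
                          baseline_log_sd = 0.8,
                          category_fold = c(progression = 3, shape = 1.5),
                          dispersion = 0.2,
                          depth_per_sample = 5e5,
                          depth_log_sd = 0.1) {
  assertCount(n_samples, "n_samples", allow_zero = FALSE)
  assertPositive(c(baseline_log_sd, dispersion), "scale parameters")
  if (depth_per_sample < 0) stop("depth_per_sample must be >= 0")
  list(n_samples = as.integer(n_samples),
       baseline_log_mean = baseline_log_mean,
       baseline_log_sd = baseline_log_sd,
       category_fold = category_fold, dispersion = dispersion,
       depth_per_sample = depth_per_sample, depth_log_sd = depth_log_sd)
}

#' @rdname bulkSimParams
#' @export
cellSimParams <- function(n_cells = 500L,
                          domain_fraction = c(progression = 0.60,
                                              shape = 0.52,
                                              tissue = 0.48,
                                              dispensable = 0.48,
                                              double = 0.48,
                                              developmental_process = 0.50,
                                              other = 0.48),
                          domain_jitter_sd = 0.6,
                          abundance_scale = c(progression = 2.5,
                                              shape = 1.2),
                          ligand_domain_multiplier = 0.5,
                          baseline_log_mean = log(5),
                          baseline_log_sd = 1.1,
                          mito_gene_fraction = 0.002,
                          mito_expression_share = 0.05,
                          damaged_cell_fraction = 0.04,
                          damaged_mito_share = 0.25,
                          depth_log_mean = log(40000),
                          depth_log_sd = 0.30,
                          dispersion = 0.5) {
  assertCount(n_cells, "n_cells")
  if (any(domain_fraction <= 0) || any(domain_fraction > 1))
    stop("domain_fraction values must lie in (0, 1]")
  assertPositive(c(abundance_scale, dispersion, ligand_domain_multiplier),
                 "scale parameters")
  if (mito_expression_share < 0 || mito_expression_share >= 1 ||
      damaged_mito_share < 0 || damaged_mito_share >= 1)
    stop("mitochondrial shares must lie in [0, 1)")
  list(n_cells = as.integer(n_cells), domain_fraction = domain_fraction,
       domain_jitter_sd = domain_jitter_sd, abundance_scale = abundance_scale,
       ligand_domain_multiplier = ligand_domain_multiplier,
       baseline_log_mean = baseline_log_mean,
       baseline_log_sd = baseline_log_sd,
       mito_gene_fraction = mito_gene_fraction,
       mito_expression_share = mito_expression_share,
       damaged_cell_fraction = damaged_cell_fraction,
       damaged_mito_share = damaged_mito_share,
       depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
       dispersion = dispersion)
}

# Expand a per-category named vector (with default 1 or given default) to a
# per-gene vector; accept an already per-gene vector unchanged.
perGene <- function(param, cats, default) {
  n <- length(cats)
  if (is.null(names(param))) {
    if (length(param) == 1L) return(rep(param, n))
    if (length(param) == n) return(as.numeric(param))
    stop("unnamed parameter vector must have length 1 or n_genes")
  }
  out <- rep(default, n)
  hit <- cats %in% names(param)
  out[hit] <- param[cats[hit]]
  out
}

#' Simulate a bulk count matrix
#'
#' Gene g in category c draws NB counts with mean proportional to
#' \code{baseline_g * category_fold[c] * depth_s}, where baselines are
#' lognormal and per-sample depths concentrate around
#' \code{depth_per_sample}.
#'
#' @param params From [bulkSimParams()].
#' @param table A \linkS4class{CategoryTable}.
#' @param seed Integer seed.
#' @param species,stage Metadata recorded on the samples.
#' @return List with \code{se} (a \link[SummarizedExperiment]{SummarizedExperiment}
#'   with integer assay \code{"counts"}) and \code{truth} (DataFrame of
#'   per-gene baseline and fold).
#' @export
simulateBulkCounts <- function(params = bulkSimParams(), table, seed = 1,
                               species = speciesTag(table), stage = "E14") {
  if (nGenes(table) == 0L) stop("category table is empty")
  cats <- unname(categories(table))
  g <- nGenes(table)
  withSeed(deriveSeed(seed, 2L), {
    baseline <- stats::rlnorm(g, params$baseline_log_mean,
                              params$baseline_log_sd)
    fold <- perGene(params$category_fold, cats, 1)
    w <- baseline * fold
    depth <- stats::rlnorm(params$n_samples,
                           log(max(params$depth_per_sample, 1e-12)) -
                             params$depth_log_sd^2 / 2,
                           params$depth_log_sd)
    if (params$depth_per_sample == 0) depth <- rep(0, params$n_samples)
    mu <- outer(w / sum(w), depth)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / params$dispersion),
                     nrow = g,
                     dimnames = list(geneIds(table),
                                     sprintf("%s_%s_rep%d", species, stage,
                                             seq_len(params$n_samples))))
    se <- makeBulkExperiment(counts, species = species, stage = stage)
    truth <- DataFrame(gene_id = geneIds(table), category = cats,
                       baseline = baseline, fold = fold)
    list(se = se, truth = truth)
  })
}

#' Simulate a sparse single-cell count matrix
#'
#' Each gene is expressed in a Bernoulli(\code{domain_fraction}) subset of
#' cells (its expression domain); conditional on expression, counts are NB
#' with mean proportional to \code{abundance_scale * baseline * cell depth}.
#' Ligand-type genes have their domain fraction multiplied by
#' \code{ligand_domain_multiplier}. A \code{mito_gene_fraction} of genes is
#' flagged mitochondrial with baselines inflated to hit
#' \code{mito_expression_share} of UMIs in expectation; a
#' \code{damaged_cell_fraction} of cells get \code{damaged_mito_share}
#' instead.
#'
#' @param params From [cellSimParams()].
#' @param table A \linkS4class{CategoryTable}.
#' @param seed Integer seed.
#' @return List with \code{sce} (a
#'   \link[SingleCellExperiment]{SingleCellExperiment}; sparse integer
#'   assay \code{"counts"}, \code{rowData()$mito} flags, per-cell
#'   \code{nUMI}/\code{nGenes} in \code{colData()}) and \code{truth}
#'   (per-gene DataFrame: domain fraction, abundance multiplier, mito flag).
#' @export
simulateCellCounts <- function(params = cellSimParams(), table, seed = 1) {
  if (nGenes(table) == 0L) stop("category table is empty")
  cats <- unname(categories(table))
  mt <- unname(moleculeTypes(table))
  g <- nGenes(table)
  nc <- params$n_cells
  withSeed(deriveSeed(seed, 3L), {
    baseline <- stats::rlnorm(g, params$baseline_log_mean,
                              params$baseline_log_sd)
    dfrac <- perGene(params$domain_fraction, cats, 0.35)
    if (params$domain_jitter_sd > 0) {
      lo <- stats::qlogis(pmin(pmax(dfrac, 1e-6), 1 - 1e-6))
      dfrac <- stats::plogis(stats::rnorm(g, lo, params$domain_jitter_sd))
    }
    dfrac <- pmin(pmax(dfrac * ifelse(mt == "ligand",
                                      params$ligand_domain_multiplier, 1),
                       1e-6), 1)
    ascale <- perGene(params$abundance_scale, cats, 1)
    n_mito <- if (params$mito_gene_fraction > 0)
      max(1L, round(params$mito_gene_fraction * g)) else 0L
    mito <- seq_len(g) %in% utils::tail(seq_len(g), n_mito)
    w <- baseline * ascale
    if (n_mito > 0) {
      s <- params$mito_expression_share
      tgt <- s / (1 - s) * sum(dfrac[!mito] * w[!mito])
      cur <- sum(dfrac[mito] * w[mito])
      w[mito] <- w[mito] * tgt / cur
    }
    depth <- stats::rlnorm(nc, params$depth_log_mean, params$depth_log_sd)
    damaged <- stats::runif(nc) < params$damaged_cell_fraction
    dmg_mult <- if (params$mito_expression_share > 0)
      (params$damaged_mito_share / (1 - params$damaged_mito_share)) /
        (params$mito_expression_share / (1 - params$mito_expression_share))
    else 1
    denom <- sum(dfrac * w)
    ip <- vector("list", nc); jp <- vector("list", nc); xp <- vector("list", nc)
    for (k in seq_len(nc)) {
      expr <- which(stats::runif(g) < dfrac)
      mu <- w[expr] * depth[k] / denom
      if (damaged[k]) mu[mito[expr]] <- mu[mito[expr]] * dmg_mult
      cnt <- stats::rnbinom(length(expr), mu = mu,
                            size = 1 / params$dispersion)
      nz <- cnt > 0L
      ip[[k]] <- expr[nz]
      jp[[k]] <- rep.int(k, sum(nz))
      xp[[k]] <- cnt[nz]
    }
    counts <- Matrix::sparseMatrix(
      i = as.integer(unlist(ip)), j = as.integer(unlist(jp)),
      x = as.numeric(unlist(xp)), dims = c(g, nc),
      dimnames = list(geneIds(table), sprintf("cell%05d", seq_len(nc))))
    sce <- makeCellExperiment(counts, mito = mito)
    truth <- DataFrame(gene_id = geneIds(table), category = cats,
                       molecule_type = mt, baseline = baseline,
                       domain_fraction = dfrac, abundance_scale = ascale,
                       mito = mito)
    list(sce = sce, truth = truth)
  })
}
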