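test_that("gene-set summaries reduce to direct computations", {
  vals <- c(gA = 1, gB = 2, gC = 9)
  expect_equal(summaryExpression(vals, c("gA", "gB", "gC")), 2)
  expect_equal(summaryExpression(vals, "gC"), 9)
  expect_equal(summaryExpression(vals, c("gA", "gB", "gC"),
                                 statistic = "mean"), 4)
  expect_error(summaryExpression(vals, character()), "empty")
  expect_error(summaryExpression(vals, "missing"), "absent")

  set.seed(1)
  v100 <- stats::setNames(rlnorm(100), paste0("g", 1:100))
  expect_equal(summaryExpression(v100, names(v100)),
               sort(v100)[50:51] |> mean())

  # cross-sample summarization: median across columns first
  m <- matrix(c(1, 10, 2, 20, 30, 3), nrow = 2,
              dimnames = list(c("x", "y"), NULL))
  expect_equal(unname(geneLevelValues(m)), c(2, 10))
  expect_equal(unname(geneLevelValues(m, "mean")), c(11, 11))
})

test_that("resampling p-values follow the add-one rule and its bounds", {
  vals <- stats::setNames(c(100, 1:20), c("hot", paste0("g", 1:20)))
  res <- resampleMedianTest(vals, focal = "hot", pool = paste0("g", 1:20),
                            n_perm = 999L, seed = 5)
  expect_equal(pValue(res), 1 / 1000)  # observed above every draw

  # focal == pool is degenerate: every draw reproduces the observed set
  res2 <- resampleMedianTest(vals, focal = paste0("g", 1:20),
                             pool = paste0("g", 1:20), n_perm = 200L,
                             seed = 1)
  expect_equal(pValue(res2), 1)

  expect_error(resampleMedianTest(vals, focal = paste0("g", 1:5),
                                  pool = paste0("g", 1:3), n_perm = 10L,
                                  seed = 1), "smaller than focal")
  expect_error(resampleMedianTest(vals, focal = character(),
                                  pool = paste0("g", 1:3), n_perm = 10L,
                                  seed = 1), "empty focal")
})

test_that("resampled p matches exhaustive enumeration on small pools", {
  set.seed(33)
  vals <- stats::setNames(round(rlnorm(8), 3), paste0("g", 1:8))
  pool <- paste0("g", 1:6)
  for (focal in list(c("g7", "g8"), c("g1", "g2"))) {
    exact <- enumerationP(vals, focal, pool)
    n_perm <- 10000L
    res <- resampleMedianTest(vals, focal, pool, n_perm = n_perm, seed = 3)
    mc_se <- sqrt(exact * (1 - exact) / n_perm)
    expect_lt(abs(pValue(res) - exact), max(2 * mc_se, 2 / n_perm))
  }
})

test_that("identical seeds give identical results; p is monotone in the observed", {
  set.seed(2)
  vals <- stats::setNames(rlnorm(40), paste0("g", 1:40))
  pool <- paste0("g", 1:30)
  a <- resampleMedianTest(vals, c("g31", "g32", "g33"), pool,
                          n_perm = 500L, seed = 77)
  b <- resampleMedianTest(vals, c("g31", "g32", "g33"), pool,
                          n_perm = 500L, seed = 77)
  expect_identical(pValue(a), pValue(b))
  expect_identical(a@nullQuantiles, b@nullQuantiles)

  # raising the focal values (pool and seed fixed) never raises p
  ps <- vapply(c(0.5, 1, 2, 5, 20), function(k) {
    v <- vals
    v[c("g31", "g32", "g33")] <- k * stats::median(vals[pool])
    pValue(resampleMedianTest(v, c("g31", "g32", "g33"), pool,
                              n_perm = 500L, seed = 77))
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("cell-level abundance implements the expressing-cell mean", {
  m <- matrix(c(0, 2, 4,
                0, 0, 0,
                7, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("gX", "gZ", "gS"), c("c1", "c2", "c3")))
  prof <- cellLevelAbundance(m)
  expect_equal(prof["gX", "x_bar"], 3)   # mean over the 2 expressing cells
  expect_equal(prof["gX", "n"], 2)
  expect_equal(prof["gX", "total"], 6)
  expect_equal(prof["gS", "x_bar"], 7)   # single expressing cell
  expect_equal(prof["gS", "n"], 1)
  expect_true(is.na(prof["gZ", "x_bar"])) # all-zero gene flagged undefined
  expect_false(prof["gZ", "defined"])
  expect_equal(prof["gZ", "n"], 0)
  expect_error(cellLevelAbundance(m, "nope"), "unknown gene")

  # the stricter "> 1" denominator variant is one argument away
  strict <- cellLevelAbundance(m, min_expr = 1)
  expect_equal(strict["gX", "n"], 2)
  expect_equal(strict["gS", "n"], 1)
})

test_that("decomposition identity total = n * x_bar holds exactly", {
  ct <- simulateCategoryTable(c(other = 300L), seed = 9)
  sim <- simulateCellCounts(cellSimParams(n_cells = 200L), ct, seed = 9)
  sce <- normalizeCells(sim$sce)
  dec <- domainDecomposition(sce)
  ok <- dec$profile$defined
  expect_identical(dec$profile$total[ok],
                   dec$profile$n[ok] * dec$profile$x_bar[ok])
  expect_true(all(is.na(dec$profile$total[!ok])))
})

test_that("domain size drives organ totals when abundance is constant", {
  ct <- simulateCategoryTable(c(other = 500L), seed = 12)
  # per-gene domain fractions spread widely, abundance flat
  par <- cellSimParams(n_cells = 500L,
                       domain_fraction = seq(0.05, 0.95, length.out = 500),
                       domain_jitter_sd = 0, abundance_scale = 1,
                       ligand_domain_multiplier = 1, mito_gene_fraction = 0,
                       mito_expression_share = 0, damaged_cell_fraction = 0,
                       baseline_log_sd = 0.05)
  sim <- simulateCellCounts(par, ct, seed = 2)
  dec <- domainDecomposition(normalizeCells(sim$sce))
  expect_gte(dec$spearman, 0.95)

  # constant domain, varying abundance: domain size no longer predicts totals
  par2 <- cellSimParams(n_cells = 500L, domain_fraction = 0.5,
                        domain_jitter_sd = 0,
                        abundance_scale = exp(seq(log(0.2), log(5),
                                                  length.out = 500)),
                        ligand_domain_multiplier = 1, mito_gene_fraction = 0,
                        mito_expression_share = 0, damaged_cell_fraction = 0,
                        baseline_log_sd = 0.2)
  sim2 <- simulateCellCounts(par2, ct, seed = 3)
  dec2 <- domainDecomposition(normalizeCells(sim2$sce))
  expect_lt(abs(dec2$spearman), 0.35)
})

test_that("abundance category test flags programmed elevation and extremes", {
  ct <- simulateCategoryTable(c(progression = 15L, dispensable = 100L),
                              seed = 21)
  par <- cellSimParams(n_cells = 400L,
                       abundance_scale = c(progression = 3, dispensable = 1),
                       domain_fraction = 0.5, domain_jitter_sd = 0.3,
                       ligand_domain_multiplier = 1)
  sim <- simulateCellCounts(par, ct, seed = 22)
  sce <- normalizeCells(sim$sce)
  res <- abundanceCategoryTest(sce, ct, "progression", "dispensable",
                               n_perm = 2000L, seed = 1)
  expect_lt(pValue(res), 0.01)
  expect_identical(res@poolSize, res@focalSize + 100L)

  # a single focal gene exceeding every pooled value attains the minimum p
  m <- matrix(1, 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  m[1, ] <- 100
  tab <- CategoryTable(gene_id = paste0("g", 1:6),
                       category = c("progression", rep("dispensable", 5)))
  # reference-only null: the extreme focal gene attains the minimum p
  res2 <- abundanceCategoryTest(m, tab, "progression", "dispensable",
                                n_perm = 1000L, seed = 2,
                                include_focal = FALSE)
  expect_equal(pValue(res2), 1 / 1001)
  # label-permutation null: draws can reproduce the focal gene itself, so
  # the tail mass converges to the focal gene's draw probability (1/6)
  res3 <- abundanceCategoryTest(m, tab, "progression", "dispensable",
                                n_perm = 5000L, seed = 2)
  expect_lt(abs(pValue(res3) - 1 / 6), 3 * sqrt(1 / 6 * 5 / 6 / 5000))
})

test_that("pathway context test isolates the ligand contribution", {
  # table: shape category half ligands; pathway pool with depressed ligands
  n_shape <- 28L; n_pool <- 120L
  tab <- CategoryTable(
    gene_id = c(sprintf("s%02d", 1:n_shape), sprintf("p%03d", 1:n_pool)),
    category = c(rep("shape", n_shape), rep("other", n_pool)),
    pathways = "Wnt",
    molecule_type = c(rep(c("ligand", "intracellular"), each = n_shape / 2),
                      rep(c("ligand", "intracellular"),
                          times = c(24, n_pool - 24))))
  # organ-level values: ligands depressed, non-ligand shape genes elevated
  set.seed(99)
  vals <- stats::setNames(rlnorm(nGenes(tab), meanlog = 0, sdlog = 0.4),
                          geneIds(tab))
  lig <- names(moleculeTypes(tab))[moleculeTypes(tab) == "ligand"]
  vals[lig] <- vals[lig] * 0.15
  shape_nonlig <- setdiff(categoryGenes(tab, "shape"), lig)
  vals[shape_nonlig] <- vals[shape_nonlig] * 2.5

  with_lig <- pathwayContextTest(vals, tab, "shape", "Wnt",
                                 exclude_ligands = FALSE,
                                 n_perm = 4000L, seed = 4)
  without_lig <- pathwayContextTest(vals, tab, "shape", "Wnt",
                                    exclude_ligands = TRUE,
                                    n_perm = 4000L, seed = 4)
  expect_gt(pValue(with_lig), 0.05)
  expect_lt(pValue(without_lig), 0.05)

  # degenerate contrast: focal category constitutes the entire pool
  tab2 <- CategoryTable(gene_id = paste0("g", 1:10), category = "shape",
                        pathways = "Fgf")
  v2 <- stats::setNames(rlnorm(10), paste0("g", 1:10))
  expect_equal(pValue(pathwayContextTest(v2, tab2, "shape", "Fgf",
                                         n_perm = 500L, seed = 1)), 1)
})

test_that("ligand domain-size test matches exact size-1 enumeration", {
  # one ligand with the smallest domain among 9 scope genes
  m <- matrix(0, 10, 30, dimnames = list(paste0("g", 1:10),
                                         paste0("c", 1:30)))
  domain_sizes <- c(2, 5:12, 30)
  for (i in 1:10) m[i, seq_len(domain_sizes[i])] <- 1
  tab <- CategoryTable(
    gene_id = paste0("g", 1:10),
    category = rep(c("progression", "shape"), 5),
    molecule_type = c("ligand", rep("receptor", 9)))
  out <- domainSizeByMoleculeType(m, tab, gene_scope = "category_genes",
                                  n_perm = 2000L, seed = 6)
  # smallest n among all scope genes: every null draw is >= observed only
  # at ties; exact enumeration over size-1 draws gives 0/9 below
  expect_equal(pValue(out$result), 1 / 2001)
  expect_identical(out$summaries$n_genes[out$summaries$molecule_type ==
                                           "ligand"], 1L)
  expect_error(domainSizeByMoleculeType(
    m, CategoryTable(gene_id = paste0("g", 1:10),
                     category = rep(c("progression", "shape"), 5),
                     molecule_type = "receptor"),
    gene_scope = "category_genes", n_perm = 100L, seed = 1), "no ligand")

  # a middling ligand: Monte Carlo tail mass matches the exact rank tail
  tab2 <- tab
  m2 <- m
  # ligand g1 now has domain size 8: exact p = #{others <= 8}/9 = 4/9
  m2[1, ] <- 0; m2[1, 1:8] <- 1
  out2 <- domainSizeByMoleculeType(m2, tab2, gene_scope = "category_genes",
                                   n_perm = 20000L, seed = 7)
  exact <- 4 / 9
  expect_lt(abs(pValue(out2$result) - exact),
            3 * sqrt(exact * (1 - exact) / 20000))
})
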