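# Fixtures built in code: tiny annotation tables and count matrices with
# hand-checkable entries.

toyTable <- function() {
  CategoryTable(
    gene_id = c("gA", "gB", "gC", "gD", "gE", "gF"),
    category = c("progression", "shape", "shape", "tissue", "dispensable",
                 "dispensable"),
    pathways = c("Wnt", "Wnt,Fgf", "", "", "Eda", ""),
    molecule_type = c("ligand", "ligand", "receptor", "other",
                      "intracellular", "unannotated"))
}

# Dense toy cell matrix wrapped as a SingleCellExperiment.
toyCells <- function(counts, mito = rep(FALSE, nrow(counts))) {
  rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("c%02d", seq_len(ncol(counts)))
  makeCellExperiment(Matrix::Matrix(counts, sparse = TRUE), mito = mito)
}

# Exact one-tailed p by exhaustive subset enumeration (the independent
# oracle for the Monte Carlo resampling engine, with the same add-one
# convention applied to the full enumeration).
enumerationP <- function(values, focal, pool, statistic = stats::median,
                         alternative = "high") {
  obs <- statistic(values[focal])
  subsets <- utils::combn(length(pool), length(focal))
  null <- apply(subsets, 2, function(ix) statistic(values[pool][ix]))
  if (alternative == "high") mean(null >= obs) else mean(null <= obs)
}

# Independent brute-force median-of-ratios, written against the definition:
# reference = geometric mean per gene over samples among all-positive genes;
# factor = median of count/reference per sample.
bruteForceSizeFactors <- function(m) {
  allpos <- apply(m, 1, function(r) all(r > 0))
  stopifnot(any(allpos))
  ref <- apply(m[allpos, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  out <- numeric(ncol(m))
  for (s in seq_len(ncol(m))) {
    ratios <- m[allpos, s] / ref
    out[s] <- sort(ratios)[ceiling(length(ratios) / 2)] * 0 +
      stats::median(ratios)
  }
  stats::setNames(out, colnames(m))
}

# Write a table to a temp TSV and return the path.
tsvFixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tabulationPath <- function() {
  system.file("extdata", "synthetic_tabulation.tsv", package = "keystoneExpr",
              mustWork = TRUE)
}
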