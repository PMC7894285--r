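## A deterministic synthetic stand-in for the published gene tabulations.

#' Synthetic stand-in for the published gene tabulations
#'
#' Builds, deterministically and without random numbers, a synthetic
#' category table whose marginal bookkeeping matches the published
#' tabulations of the tooth keystone-gene classification: 15 progression,
#' 28 shape, 27 tissue, and 100 dispensable genes, 11 double-category
#' genes, 272 genes in the union of the six signaling pathways (Wnt, Tgfb,
#' Fgf, Hh, Eda, Notch), 221 genes in the union of the four families
#' containing the progression genes (Wnt, Tgfb, Fgf, Hh), and ligand
#' fractions of 3/15 = 20\% (progression) and 10/28 = 36\% after rounding
#' (shape). Gene identifiers are synthetic; the table carries no curated
#' biology beyond these counts and is intended for tests, examples, and
#' structural validation. The same table ships as
#' \code{inst/extdata/synthetic_tabulation.tsv}.
#'
#' @return A \linkS4class{CategoryTable}.
#' @examples
#' tab <- syntheticTabulationTable()
#' countByCategory(tab)
#' length(pathwayGeneSet(tab, allPathways()))
#' @export
syntheticTabulationTable <- function() {
  four <- c("Wnt", "Tgfb", "Fgf", "Hh")
  two <- c("Eda", "Notch")
  cyc <- function(set, n) rep_len(set, n)
  blocks <- list(
    # 15 progression genes in the four families; 3 ligands (20%)
    list(cat = "progression", n = 15L, pw = cyc(four, 15),
         mt = c(rep("ligand", 3), cyc(c("receptor", "intracellular",
                                        "transcription_factor"), 12))),
    # 28 shape genes; 10 ligands (36% at two decimals); 20 in the four
    # families, 8 only in Eda/Notch
    list(cat = "shape", n = 28L, pw = c(cyc(four, 20), cyc(two, 8)),
         mt = c(rep("ligand", 10), cyc(c("receptor", "intracellular",
                                         "transcription_factor"), 18))),
    # 27 tissue genes: hard-tissue matrix components, outside the pathways
    list(cat = "tissue", n = 27L, pw = "",
         mt = cyc(c("other", "intracellular"), 27)),
    # 100 dispensable genes
    list(cat = "dispensable", n = 100L, pw = "",
         mt = c(rep("ligand", 12), cyc(c("receptor", "intracellular",
                                         "transcription_factor", "other"),
                                       88))),
    # 11 double-category genes (paralog pairs + one heterozygous pair)
    list(cat = "double", n = 11L, pw = "",
         mt = cyc(c("intracellular", "transcription_factor", "ligand"), 11)),
    # pathway members beyond the keystone sets: 186 more in the four
    # families (15 + 20 + 186 = 221) and 43 more in Eda/Notch only
    # (221 + 8 + 43 = 272)
    list(cat = "other", n = 186L, pw = cyc(four, 186),
         mt = c(rep("ligand", 40), cyc(c("receptor", "intracellular",
                                         "transcription_factor"), 146))),
    list(cat = "other", n = 43L, pw = cyc(two, 43),
         mt = c(rep("ligand", 9), cyc(c("receptor", "intracellular",
                                        "transcription_factor"), 34))),
    # a developmental-process control pool
    list(cat = "developmental_process", n = 120L, pw = "",
         mt = cyc(c("intracellular", "transcription_factor", "receptor",
                    "other"), 120))
  )
  cat_v <- unlist(lapply(blocks, function(b) rep(b$cat, b$n)))
  pw_v <- unlist(lapply(blocks, function(b) rep_len(b$pw, b$n)))
  mt_v <- unlist(lapply(blocks, function(b) rep_len(b$mt, b$n)))
  ids <- sprintf("SYN%04d", seq_along(cat_v))
  CategoryTable(gene_id = ids, category = cat_v, pathways = pw_v,
                molecule_type = mt_v, species = "synthetic-mouse")
}
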