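# Reference results shipped with the package: the per-cell c-index grid
# and the merged-model feature compositions reported by a published
# four-cancer TCGA benchmark (OV, LUAD, BRCA, GBM). They serve as inputs
# for worked examples and for the table-arithmetic checks (margin averages,
# pooled source shares); the cohort-level values themselves depend on the
# original TCGA data and are not recomputed here.

#' Reference c-index grid (published four-cancer TCGA benchmark)
#'
#' One row per (cohort, algorithm, data type) cell: the c-index on the
#' 0-100 integer scale and the log-rank significance tier
#' (\code{a}/\code{b}/\code{c} for p < 0.05/0.01/0.001, \code{none}
#' otherwise). The single \code{NA} cell is a selector run that generated
#' no model.
#'
#' @return A data.frame with columns \code{cohort}, \code{algorithm},
#'   \code{datatype}, \code{cindex}, \code{tier}.
#' @export
referenceCindexGrid <- function() {
  read.delim(system.file("extdata", "published_cindex_grid.tsv",
                         package = "survomics"),
             stringsAsFactors = FALSE)
}

#' Reference merged-model compositions (published benchmark)
#'
#' Feature counts per source for each best model trained on the merged
#' (MERGE) data: one row per (algorithm, cohort) with the model size and
#' its EXPR/MIRNA/CNA/MUT feature counts.
#'
#' @return A data.frame with columns \code{algorithm}, \code{cohort},
#'   \code{size}, \code{EXPR}, \code{MIRNA}, \code{CNA}, \code{MUT}.
#' @export
referenceMergeModels <- function() {
  read.delim(system.file("extdata", "published_merge_models.tsv",
                         package = "survomics"),
             stringsAsFactors = FALSE)
}
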