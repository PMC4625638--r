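# TSV dialect: tab-separated, UTF-8, no quoting, '.' decimal point.
# Matrix files: first column `feature_id`, remaining columns patient ids.

#' Read a feature-by-patient matrix from TSV
#'
#' @param path TSV file: header row \code{feature_id} followed by patient
#'   ids; one row per feature.
#' @param source data type tag (\code{"EXPR"}, \code{"MIRNA"}, \code{"CNA"},
#'   \code{"MUT"} or \code{"MERGE"}); MUT values are validated as binary.
#' @return An \linkS4class{OmicsMatrix}.
#' @export
readOmicsMatrix <- function(path, source) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "feature_id")
    stop("matrix TSV must start with a 'feature_id' column")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals))
    stop("non-numeric cells in ", path)
  rownames(vals) <- ids
  if (anyDuplicated(colnames(vals)))
    stop("duplicate patient ids in ", path)
  if (identical(source, "MUT") && !all(vals %in% c(0, 1)))
    stop("MUT matrix contains non-binary values")
  if (identical(source, "MERGE")) {
    src <- sub(":.*$", "", ids)
    OmicsMatrix(vals, "MERGE", featureSources = setNames(src, ids))
  } else {
    OmicsMatrix(vals, source)
  }
}

#' Write a feature-by-patient matrix to TSV
#'
#' @param x an \linkS4class{OmicsMatrix}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeOmicsMatrix <- function(x, path) {
  v <- omicsValues(x)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a clinical survival table
#'
#' The clinical TSV has the header \code{patient_id<TAB>time<TAB>event}.
#'
#' @param path TSV file path.
#' @return \code{readSurvivalData}: a \linkS4class{SurvivalData}.
#' @export
readSurvivalData <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("clinical TSV must have columns patient_id, time, event")
  SurvivalData(df$patient_id, df$time, df$event)
}

#' @rdname readSurvivalData
#' @param x a \linkS4class{SurvivalData}.
#' @export
writeSurvivalData <- function(x, path) {
  df <- data.frame(patient_id = patientIds(x), time = x@time,
                   event = x@event)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write an interaction network as a 2-column edge list
#'
#' @param path TSV edge-list path (two columns, no header).
#' @return \code{readInteractionNetwork}: an
#'   \linkS4class{InteractionNetwork}.
#' @export
readInteractionNetwork <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, colClasses = "character")
  InteractionNetwork(df)
}

#' @rdname readInteractionNetwork
#' @param x an \linkS4class{InteractionNetwork}.
#' @export
writeInteractionNetwork <- function(x, path) {
  el <- igraph::as_edgelist(networkGraph(x))
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read/write a miRNA target map as a 2-column TSV
#'
#' Columns: \code{mirna_id}, \code{gene_id}; one row per link.
#'
#' @param path TSV file path.
#' @return \code{readMirnaTargets}: a \linkS4class{MirnaTargetMap}.
#' @export
readMirnaTargets <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("mirna_id", "gene_id") %in% names(df)))
    stop("target TSV must have columns mirna_id, gene_id")
  MirnaTargetMap(split(df$gene_id, df$mirna_id))
}

#' @rdname readMirnaTargets
#' @param x a \linkS4class{MirnaTargetMap}.
#' @export
writeMirnaTargets <- function(x, path) {
  t <- mirnaTargets(x)
  df <- data.frame(mirna_id = rep(names(t), lengths(t)),
                   gene_id = unlist(t, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict all sources and survival to their common patients
#'
#' Drops patients not present in every matrix and in the survival table, and
#' puts everything in one canonical (lexicographic) patient order, mirroring
#' the inclusion rule that only subjects with all four data types available
#' enter the analysis.
#'
#' @param matrices named list of \linkS4class{OmicsMatrix} objects.
#' @param survival a \linkS4class{SurvivalData}.
#' @return List with elements \code{matrices} and \code{survival}, aligned.
#' @export
alignCohort <- function(matrices, survival) {
  ids <- Reduce(intersect, c(lapply(matrices, patientIds),
                             list(patientIds(survival))))
  if (length(ids) == 0L)
    stop("no patients shared by all matrices and the survival table")
  ids <- sort(ids)
  surv <- SurvivalData(ids, survTime(survival)[ids], survEvent(survival)[ids])
  mats <- lapply(matrices, function(m)
    OmicsMatrix(omicsValues(m)[, ids, drop = FALSE], omicsSource(m),
                featureSources = featureSources(m)))
  list(matrices = mats, survival = surv)
}

#' Quantile-normalize a continuous omics matrix
#'
#' Forces every patient (column) onto the mean order-statistic distribution;
#' ties within a column receive the mean of the order statistics they span.
#' Delegates to \code{\link[limma]{normalizeQuantiles}}.
#'
#' @param x an \linkS4class{OmicsMatrix} with a continuous source (EXPR,
#'   MIRNA or CNA); MUT matrices are rejected.
#' @return The normalized \linkS4class{OmicsMatrix}.
#' @export
quantileNormalize <- function(x) {
  if (!omicsSource(x) %in% continuousSources)
    stop("quantile normalization applies only to continuous sources")
  v <- omicsValues(x)
  nv <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(nv) <- dimnames(v)
  OmicsMatrix(nv, omicsSource(x), featureSources = featureSources(x))
}
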