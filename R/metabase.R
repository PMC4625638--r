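# The metabase (MERGE) is the row-concatenation of the filtered
# single-source matrices over a shared patient order, with feature ids
# prefixed by their source tag so the origin of every selected feature
# stays recoverable.

#' Build the merged (MERGE) matrix from filtered single-source matrices
#'
#' Row-concatenates the inputs with source-prefixed feature ids
#' (\code{EXPR:}, \code{MIRNA:}, \code{CNA:}, \code{MUT:}). Values are
#' untouched and no re-normalization happens at merge time. All inputs must
#' share the identical patient order.
#'
#' @param filtered named list of \linkS4class{OmicsMatrix} objects (names =
#'   source tags); empty matrices are allowed.
#' @return An \linkS4class{OmicsMatrix} with source \code{"MERGE"} and a
#'   per-feature source lookup.
#' @export
buildMetabase <- function(filtered) {
  stopifnot(length(filtered) >= 1L)
  pats <- patientIds(filtered[[1]])
  for (m in filtered) {
    if (!identical(patientIds(m), pats))
      stop("patient order mismatch between sources")
  }
  blocks <- lapply(names(filtered), function(s) {
    v <- omicsValues(filtered[[s]])
    if (nrow(v)) rownames(v) <- paste0(s, ":", rownames(v))
    v
  })
  v <- do.call(rbind, blocks)
  src <- unlist(lapply(names(filtered), function(s)
    rep(s, nrow(omicsValues(filtered[[s]])))), use.names = FALSE)
  OmicsMatrix(v, "MERGE", featureSources = setNames(src, rownames(v)))
}

#' Project a merged matrix back onto one source
#'
#' @param merged a MERGE \linkS4class{OmicsMatrix} from
#'   \code{\link{buildMetabase}}.
#' @param source source tag to extract.
#' @return The single-source \linkS4class{OmicsMatrix} with unprefixed
#'   feature ids.
#' @export
projectSource <- function(merged, source) {
  stopifnot(identical(omicsSource(merged), "MERGE"))
  keep <- featureSources(merged) == source
  v <- omicsValues(merged)[keep, , drop = FALSE]
  rownames(v) <- sub("^[A-Z]+:", "", rownames(v))
  OmicsMatrix(v, source)
}

# strip the source prefix from a merged feature id
baseFeatureId <- function(ids) sub("^(EXPR|MIRNA|CNA|MUT):", "", ids)
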