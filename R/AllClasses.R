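#' OmicsMatrix: one genomic source's feature-by-patient matrix
#'
#' Container for a single data source. Rows are features, columns are
#' patients; the source tag records the data type and drives validation
#' (mutation matrices must be strictly 0/1).
#'
#' @slot source character(1), one of \code{"EXPR"}, \code{"MIRNA"},
#'   \code{"CNA"}, \code{"MUT"} or \code{"MERGE"}.
#' @slot values numeric matrix, features x patients, with unique row and
#'   column names (feature and patient ids).
#' @slot featureSources named character vector mapping each feature id to
#'   its originating source; used by merged matrices, and identical to the
#'   source tag for single-source matrices.
#'
#' @aliases OmicsMatrix-class
#' @exportClass OmicsMatrix
setClass("OmicsMatrix",
  representation(source = "character",
                 values = "matrix",
                 featureSources = "character"))

validOmicsSources <- c("EXPR", "MIRNA", "CNA", "MUT", "MERGE")
continuousSources <- c("EXPR", "MIRNA", "CNA")

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (length(object@source) != 1L || !object@source %in% validOmicsSources)
    msg <- c(msg, sprintf("source must be one of %s",
                          paste(validOmicsSources, collapse = ", ")))
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if ((nrow(v) > 0L && is.null(rownames(v))) ||
      (ncol(v) > 0L && is.null(colnames(v))))
    msg <- c(msg, "values must have feature (row) and patient (column) names")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate feature ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate patient ids")
  }
  if (anyNA(v)) msg <- c(msg, "missing values are not allowed")
  if (identical(object@source, "MUT") && !all(v %in% c(0, 1)))
    msg <- c(msg, "MUT matrices must contain only 0/1 values")
  rn <- rownames(v); if (is.null(rn)) rn <- character()
  fn <- names(object@featureSources); if (is.null(fn)) fn <- character()
  if (length(object@featureSources) != nrow(v) || !identical(fn, rn))
    msg <- c(msg, "featureSources must be named by the feature ids")
  if (length(msg)) msg else TRUE
})

#' SurvivalData: right-censored follow-up for a patient cohort
#'
#' @slot patientIds character vector of unique patient ids.
#' @slot time positive follow-up times (same units throughout a cohort;
#'   days for the synthetic generator).
#' @slot event 0/1 event indicators (1 = event observed, 0 = censored).
#'
#' @aliases SurvivalData-class
#' @exportClass SurvivalData
setClass("SurvivalData",
  representation(patientIds = "character",
                 time = "numeric",
                 event = "integer"))

setValidity("SurvivalData", function(object) {
  msg <- character()
  n <- length(object@patientIds)
  if (anyDuplicated(object@patientIds)) msg <- c(msg, "duplicate patient ids")
  if (length(object@time) != n || length(object@event) != n)
    msg <- c(msg, "time and event must match patientIds in length")
  if (any(!is.finite(object@time)) || any(object@time <= 0))
    msg <- c(msg, "times must be positive and finite")
  if (!all(object@event %in% c(0L, 1L)))
    msg <- c(msg, "event must be 0/1")
  if (length(msg)) msg else TRUE
})

#' InteractionNetwork: undirected feature interaction graph
#'
#' Wraps an undirected \pkg{igraph} graph over feature ids (gene symbols or
#' miRNA ids). Used by the network-guided selector to constrain model growth
#' to connected subgraphs.
#'
#' @slot graph an undirected, simple \code{igraph} object with a \code{name}
#'   vertex attribute.
#'
#' @aliases InteractionNetwork-class
#' @exportClass InteractionNetwork
setClass("InteractionNetwork", representation(graph = "ANY"))

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (!igraph::is_igraph(g)) msg <- c(msg, "graph must be an igraph object")
  else {
    if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
    if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops not allowed")
    if (is.null(igraph::V(g)$name)) msg <- c(msg, "vertices must be named")
  }
  if (length(msg)) msg else TRUE
})

#' MirnaTargetMap: miRNA to target-gene mapping
#'
#' @slot targets named list; names are miRNA ids, elements are non-empty
#'   character vectors of target gene ids.
#'
#' @aliases MirnaTargetMap-class
#' @exportClass MirnaTargetMap
setClass("MirnaTargetMap", representation(targets = "list"))

setValidity("MirnaTargetMap", function(object) {
  t <- object@targets
  msg <- character()
  if (length(t)) {
    if (is.null(names(t)) || any(!nzchar(names(t))) || anyDuplicated(names(t)))
      msg <- c(msg, "targets must be uniquely named by miRNA id")
    ok <- vapply(t, function(x) is.character(x) && length(x) > 0L &&
                   all(nzchar(x)), logical(1))
    if (!all(ok)) msg <- c(msg, "every miRNA must map to >= 1 gene id")
  }
  if (length(msg)) msg else TRUE
})

#' CoxFit: a fitted multivariate Cox proportional hazards model
#'
#' @slot featureIds covariate (feature) ids, in model order.
#' @slot beta log-hazard coefficients, one per feature (aliased covariates
#'   carry 0 and flip \code{converged} to \code{FALSE}).
#' @slot se coefficient standard errors (NA where unavailable).
#' @slot loglik length-2: null and fitted partial log-likelihood.
#' @slot converged logical convergence flag.
#' @slot nEvents number of events in the fitting data.
#'
#' @aliases CoxFit-class
#' @exportClass CoxFit
setClass("CoxFit",
  representation(featureIds = "character", beta = "numeric", se = "numeric",
                 loglik = "numeric", converged = "logical",
                 nEvents = "integer"))

setValidity("CoxFit", function(object) {
  msg <- character()
  if (length(object@beta) != length(object@featureIds))
    msg <- c(msg, "beta length must equal number of features")
  if (isTRUE(object@converged) && any(!is.finite(object@beta)))
    msg <- c(msg, "converged fits must have finite coefficients")
  if (length(msg)) msg else TRUE
})

#' SurvivalModel: a selected feature set with Cox coefficients
#'
#' The common output of the three selectors: the chosen features (with their
#' source tags), coefficients refit on the training data, the selector's
#' internal fitness, and bookkeeping for downstream evaluation.
#'
#' @slot featureIds selected feature ids.
#' @slot featureSources source tag per selected feature.
#' @slot beta Cox log-hazard coefficients for the selected features.
#' @slot method \code{"CPSO"}, \code{"NFS"} or \code{"LASSO"}.
#' @slot fitness the selector's internal score for the winning model
#'   (bootstrap c-index for CPSO, likelihood-ratio p-value for NFS,
#'   cross-validated deviance for LASSO).
#' @slot trainIds patient ids the model was trained on.
#' @slot meta list of selector-specific diagnostics.
#'
#' @aliases SurvivalModel-class
#' @exportClass SurvivalModel
setClass("SurvivalModel",
  representation(featureIds = "character", featureSources = "character",
                 beta = "numeric", method = "character", fitness = "numeric",
                 trainIds = "character", meta = "list"))

setValidity("SurvivalModel", function(object) {
  msg <- character()
  k <- length(object@featureIds)
  if (length(object@beta) != k || length(object@featureSources) != k)
    msg <- c(msg, "beta and featureSources must match featureIds in length")
  if (length(object@method) != 1L)
    msg <- c(msg, "method must be a single string")
  if (length(msg)) msg else TRUE
})

#' EvalResult: performance summary of one survival model
#'
#' @slot cIndex Harrell's concordance index in [0, 1].
#' @slot logrankChi2 1-df log-rank chi-square of the median-split risk
#'   groups.
#' @slot logrankP log-rank p-value.
#' @slot tier significance tier: \code{"none"}, \code{"a"} (p < 0.05),
#'   \code{"b"} (p < 0.01) or \code{"c"} (p < 0.001).
#' @slot prognosticIndex named per-patient linear predictor used for the
#'   risk split and for agreement analysis.
#' @slot mode \code{"blind_test"} or \code{"resubstitution"}.
#'
#' @aliases EvalResult-class
#' @exportClass EvalResult
setClass("EvalResult",
  representation(cIndex = "numeric", logrankChi2 = "numeric",
                 logrankP = "numeric", tier = "character",
                 prognosticIndex = "numeric", mode = "character"))

setValidity("EvalResult", function(object) {
  msg <- character()
  if (!object@tier %in% c("none", "a", "b", "c"))
    msg <- c(msg, "tier must be none/a/b/c")
  if (!object@mode %in% c("blind_test", "resubstitution"))
    msg <- c(msg, "mode must be blind_test or resubstitution")
  if (is.finite(object@cIndex) &&
      (object@cIndex < 0 || object@cIndex > 1))
    msg <- c(msg, "cIndex must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
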