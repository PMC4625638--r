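#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, features in rows, patients in columns, with
#'   unique dimnames.
#' @param source data type tag: \code{"EXPR"}, \code{"MIRNA"}, \code{"CNA"},
#'   \code{"MUT"} or \code{"MERGE"}.
#' @param featureSources optional named character vector giving the source
#'   of each feature; defaults to the matrix-level source tag.
#' @return An \linkS4class{OmicsMatrix}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("P1", "P2")))
#' OmicsMatrix(m, "EXPR")
#' @export
OmicsMatrix <- function(values, source, featureSources = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(featureSources)) {
    featureSources <- setNames(rep(source, nrow(values)), rownames(values))
  }
  new("OmicsMatrix", source = source, values = values,
      featureSources = featureSources)
}

#' Construct a SurvivalData object
#'
#' @param patientIds unique patient identifiers.
#' @param time positive follow-up times.
#' @param event 0/1 event indicators (1 = event observed).
#' @return A \linkS4class{SurvivalData}.
#' @export
SurvivalData <- function(patientIds, time, event) {
  new("SurvivalData", patientIds = as.character(patientIds),
      time = as.numeric(time), event = as.integer(event))
}

#' Construct an InteractionNetwork from an edge list
#'
#' Self-loops and duplicate edges are removed; isolated nodes may be added
#' through \code{nodes}.
#'
#' @param edges two-column character matrix or data.frame of undirected
#'   edges over feature ids.
#' @param nodes optional additional node ids (isolated nodes allowed).
#' @return An \linkS4class{InteractionNetwork}.
#' @export
InteractionNetwork <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || NROW(edges) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    if (length(nodes)) g <- igraph::add_vertices(g, length(nodes),
                                                 name = unique(as.character(nodes)))
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    extra <- setdiff(unique(as.character(nodes)), igraph::V(g)$name)
    if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  new("InteractionNetwork", graph = g)
}

#' Construct a MirnaTargetMap
#'
#' @param targets named list mapping each miRNA id to a character vector of
#'   target gene ids (empty target sets are rejected).
#' @return A \linkS4class{MirnaTargetMap}.
#' @export
MirnaTargetMap <- function(targets = list()) {
  targets <- lapply(targets, function(x) unique(as.character(x)))
  new("MirnaTargetMap", targets = targets)
}

#' @rdname featureIds
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname patientIds
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname omicsValues
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))

#' @rdname omicsSource
#' @export
setGeneric("omicsSource", function(x) standardGeneric("omicsSource"))

#' @rdname featureSources
#' @export
setGeneric("featureSources", function(x) standardGeneric("featureSources"))

#' Feature ids of a container
#'
#' @param x an \linkS4class{OmicsMatrix}, \linkS4class{SurvivalModel} or
#'   \linkS4class{CoxFit}.
#' @return Character vector of feature ids.
#' @name featureIds
#' @aliases featureIds,OmicsMatrix-method featureIds,SurvivalModel-method
#'   featureIds,CoxFit-method
#' @export
setMethod("featureIds", "OmicsMatrix", function(x) rownames(x@values))
setMethod("featureIds", "SurvivalModel", function(x) x@featureIds)
setMethod("featureIds", "CoxFit", function(x) x@featureIds)

#' Patient ids of a container
#'
#' @param x an \linkS4class{OmicsMatrix} or \linkS4class{SurvivalData}.
#' @return Character vector of patient ids.
#' @name patientIds
#' @aliases patientIds,OmicsMatrix-method patientIds,SurvivalData-method
#' @export
setMethod("patientIds", "OmicsMatrix", function(x) colnames(x@values))
setMethod("patientIds", "SurvivalData", function(x) x@patientIds)

#' Value matrix of an OmicsMatrix
#'
#' @param x an \linkS4class{OmicsMatrix}.
#' @return Numeric matrix, features x patients.
#' @name omicsValues
#' @aliases omicsValues,OmicsMatrix-method
#' @export
setMethod("omicsValues", "OmicsMatrix", function(x) x@values)

#' Source tag of an OmicsMatrix
#'
#' @param x an \linkS4class{OmicsMatrix}.
#' @return Single source string.
#' @name omicsSource
#' @aliases omicsSource,OmicsMatrix-method
#' @export
setMethod("omicsSource", "OmicsMatrix", function(x) x@source)

#' Per-feature source lookup
#'
#' @param x an \linkS4class{OmicsMatrix} or \linkS4class{SurvivalModel}.
#' @return Named character vector: feature id -> source tag.
#' @name featureSources
#' @aliases featureSources,OmicsMatrix-method featureSources,SurvivalModel-method
#' @export
setMethod("featureSources", "OmicsMatrix", function(x) x@featureSources)
setMethod("featureSources", "SurvivalModel", function(x)
  setNames(x@featureSources, x@featureIds))

#' Survival times and event indicators
#'
#' @param x a \linkS4class{SurvivalData}.
#' @return Numeric vector of times / integer 0-1 vector of event flags,
#'   named by patient id.
#' @export
survTime <- function(x) setNames(x@time, x@patientIds)

#' @rdname survTime
#' @export
survEvent <- function(x) setNames(x@event, x@patientIds)

#' Coefficients of a fit or model
#'
#' @param object a \linkS4class{CoxFit} or \linkS4class{SurvivalModel}.
#' @param ... unused.
#' @return Named numeric vector of log-hazard coefficients.
#' @aliases coef,CoxFit-method coef,SurvivalModel-method
#' @export
setMethod("coef", "CoxFit", function(object, ...)
  setNames(object@beta, object@featureIds))
setMethod("coef", "SurvivalModel", function(object, ...)
  setNames(object@beta, object@featureIds))

#' Interaction graph of a network
#'
#' @param x an \linkS4class{InteractionNetwork}.
#' @return The underlying undirected \code{igraph} object.
#' @export
networkGraph <- function(x) x@graph

#' Degree lookup for a network
#'
#' @param x an \linkS4class{InteractionNetwork}.
#' @param ids optional feature ids; ids absent from the network get degree 0.
#' @return Named integer vector of degrees.
#' @export
networkDegree <- function(x, ids = NULL) {
  g <- x@graph
  d <- setNames(igraph::degree(g), igraph::V(g)$name)
  if (is.null(ids)) return(d)
  out <- setNames(integer(length(ids)), ids)
  hit <- intersect(ids, names(d))
  out[hit] <- d[hit]
  out
}

#' Targets of each miRNA
#'
#' @param x a \linkS4class{MirnaTargetMap}.
#' @return Named list of character vectors.
#' @export
mirnaTargets <- function(x) x@targets

setMethod("show", "OmicsMatrix", function(object) {
  cat(sprintf("OmicsMatrix [%s]: %d features x %d patients\n",
              object@source, nrow(object@values), ncol(object@values)))
  if (identical(object@source, "MERGE")) {
    tab <- table(object@featureSources)
    cat("  sources:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  }
})

setMethod("show", "SurvivalData", function(object) {
  cat(sprintf("SurvivalData: %d patients, %d events (%.1f%% censored)\n",
              length(object@patientIds), sum(object@event),
              100 * mean(object@event == 0L)))
})

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork: %d nodes, %d edges\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph)))
})

setMethod("show", "MirnaTargetMap", function(object) {
  cat(sprintf("MirnaTargetMap: %d miRNAs, %d target links\n",
              length(object@targets),
              sum(lengths(object@targets))))
})

setMethod("show", "SurvivalModel", function(object) {
  cat(sprintf("SurvivalModel [%s]: %d features (fitness %.4g)\n",
              object@method, length(object@featureIds), object@fitness))
  if (length(object@featureIds)) {
    df <- data.frame(feature = object@featureIds,
                     source = object@featureSources,
                     beta = signif(object@beta, 4))
    print(head(df, 10), row.names = FALSE)
    if (length(object@featureIds) > 10) cat("  ...\n")
  }
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult [%s]: c-index %.3f, log-rank chi2 %.3f (p %.3g, tier %s)\n",
              object@mode, object@cIndex, object@logrankChi2,
              object@logrankP, object@tier))
})

setMethod("show", "CoxFit", function(object) {
  cat(sprintf("CoxFit: %d covariates, %d events, %sconverged\n",
              length(object@featureIds), object@nEvents,
              if (object@converged) "" else "NOT "))
})
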