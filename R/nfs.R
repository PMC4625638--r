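# Network-guided forward growth of Cox models. Every feature starts as a
# single-feature model; each generation, models grow by one network
# neighbor at a time, candidates are scored by the likelihood-ratio p-value
# of their multivariate Cox fit against the null model, and the top
# fraction survives to grow again. High-degree hub genes are never added.

#' Configuration for the network selector
#'
#' @param topFraction fraction of grown candidate models kept per
#'   generation (default 0.05, the "top 5\%").
#' @param maxIterations growth generations (default 10).
#' @param hubDegreeLimit genes with more network connections than this are
#'   not allowed to grow into models (default 1000).
#' @param seed integer seed (used only for tie shuffling stability).
#' @return A validated list of class \code{nfs_config}.
#' @export
nfsConfig <- function(topFraction = 0.05, maxIterations = 10L,
                      hubDegreeLimit = 1000L, seed = 1L) {
  assertFraction(topFraction, "topFraction")
  assertScalarCount(maxIterations, "maxIterations")
  assertScalarCount(hubDegreeLimit, "hubDegreeLimit")
  structure(list(topFraction = topFraction,
                 maxIterations = as.integer(maxIterations),
                 hubDegreeLimit = as.integer(hubDegreeLimit),
                 seed = as.integer(seed)),
            class = "nfs_config")
}

#' Build the miRNA surrogate interaction network
#'
#' Protein-protein interactions carry over to miRNAs through their targets:
#' for every miRNA m targeting gene g, m inherits all of g's edges (the
#' mRNA is replaced by the miRNA that regulates it). Gene-gene edges are
#' retained and no self-loops are introduced; miRNAs without targets in the
#' graph become isolated nodes.
#'
#' @param ppi an \linkS4class{InteractionNetwork} over gene ids.
#' @param targets a \linkS4class{MirnaTargetMap}; miRNA ids must be
#'   disjoint from the gene namespace.
#' @return An \linkS4class{InteractionNetwork} over genes and miRNAs.
#' @export
buildSurrogateNetwork <- function(ppi, targets) {
  g <- networkGraph(ppi)
  genes <- igraph::V(g)$name
  tmap <- mirnaTargets(targets)
  if (length(intersect(names(tmap), genes)))
    stop("miRNA ids must be disjoint from gene ids")
  edges <- igraph::as_edgelist(g)
  new_edges <- list()
  for (m in names(tmap)) {
    for (tg in intersect(tmap[[m]], genes)) {
      nb <- setdiff(igraph::V(g)$name[
        as.integer(igraph::neighbors(g, tg))], m)
      if (length(nb))
        new_edges[[length(new_edges) + 1L]] <- cbind(m, nb)
    }
  }
  all_edges <- rbind(edges,
                     if (length(new_edges)) do.call(rbind, new_edges))
  InteractionNetwork(all_edges, nodes = c(genes, names(tmap)))
}

#' Univariate Cox screen
#'
#' Wald p-value of a single-feature Cox model for every feature; failed or
#' degenerate fits (constant covariates, non-convergence) degrade to p = 1
#' with a warning-free fallback.
#'
#' @param x patients x features matrix.
#' @param survival aligned \linkS4class{SurvivalData}.
#' @return Named vector of p-values.
#' @export
univariateScreen <- function(x, survival) {
  vapply(colnames(x), function(f) {
    v <- x[, f]
    if (sd(v) == 0) return(1)
    fit <- tryCatch(suppressWarnings(
      fitCox(x[, f, drop = FALSE], survival)), error = function(e) NULL)
    if (is.null(fit) || !fit@converged) return(1)
    p <- unname(coxWaldP(fit))
    if (!is.finite(p)) 1 else p
  }, numeric(1))
}

adjacencyList <- function(network) {
  g <- networkGraph(network)
  nodes <- igraph::V(g)$name
  lapply(setNames(seq_along(nodes), nodes), function(i)
    nodes[as.integer(igraph::neighbors(g, i))])
}

# neighbors of a model's feature set in the expanded network, subject to
# hub exclusion and availability in the data
eligibleNeighbors <- function(members, adj, degrees, hubLimit, available) {
  nb <- unique(unlist(adj[members], use.names = FALSE))
  nb <- setdiff(nb, members)
  nb <- nb[nb %in% available]
  nb[degrees[nb] <= hubLimit]
}

# score a feature set: LRT p-value of the multivariate Cox fit (smaller is
# better); Inf on failure
scoreModel <- function(members, x, survival) {
  fit <- tryCatch(suppressWarnings(
    fitCox(x[, members, drop = FALSE], survival)), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit@loglik)) return(Inf)
  p <- coxLrtP(fit)
  if (!is.finite(p)) Inf else p
}

#' Grow candidate models by one network neighbor
#'
#' For every current model, creates one candidate per eligible neighbor of
#' any member (not already in the model, network degree within the hub
#' limit, present in the data). Candidates are deduplicated by feature set,
#' scored by multivariate LRT p-value, and the top
#' \code{ceiling(topFraction * n)} survive.
#'
#' @param current list of models; each a list with \code{members} and
#'   \code{score}.
#' @param network an \linkS4class{InteractionNetwork}.
#' @param x patients x features matrix.
#' @param survival aligned \linkS4class{SurvivalData}.
#' @param config an \code{\link{nfsConfig}}.
#' @return List of surviving grown models (possibly empty).
#' @export
growModels <- function(current, network, x, survival, config) {
  adj <- adjacencyList(network)
  degrees <- networkDegree(network, colnames(x))
  available <- colnames(x)
  sets <- list(); keys <- character()
  for (mod in current) {
    nbs <- eligibleNeighbors(mod$members, adj, degrees,
                             config$hubDegreeLimit, available)
    for (nb in nbs) {
      members <- c(mod$members, nb)
      key <- paste(sort(members), collapse = "|")
      if (!key %in% keys) {
        keys <- c(keys, key)
        sets[[length(sets) + 1L]] <- members
      }
    }
  }
  if (!length(sets)) return(list())
  scores <- vapply(sets, scoreModel, numeric(1), x = x, survival = survival)
  keep <- fractionCount(config$topFraction, length(sets))
  ord <- order(scores, keys)
  lapply(ord[seq_len(min(keep, length(sets)))], function(i)
    list(members = sets[[i]], score = scores[i]))
}

#' Run the network feature selector
#'
#' Seeds one single-feature model per feature, then repeatedly grows the
#' surviving models along the interaction network (one neighbor per step,
#' hubs excluded, top fraction kept per generation) until no model can grow
#' or the iteration cap is reached. Returns the best-scoring model observed
#' at any generation, refit on the training data.
#'
#' @param x patients x features training matrix.
#' @param survival aligned \linkS4class{SurvivalData}.
#' @param network an \linkS4class{InteractionNetwork}; for miRNA or merged
#'   data pass the surrogate/expanded network (see
#'   \code{\link{buildSurrogateNetwork}} and
#'   \code{\link{expandNetworkToFeatures}}).
#' @param config an \code{\link{nfsConfig}}.
#' @param featureSources optional named source lookup for the features.
#' @return A \linkS4class{SurvivalModel} with method \code{"NFS"}; fitness
#'   is the winning model's LRT p-value (smaller is better).
#' @export
runNfs <- function(x, survival, network, config = nfsConfig(),
                   featureSources = NULL) {
  # seeds are one-feature models, scored with the same model-level LRT
  # criterion used for grown candidates so sizes compare consistently
  seeds <- lapply(colnames(x), function(f)
    list(members = f, score = scoreModel(f, x, survival)))
  bestScore <- Inf; bestMembers <- NULL; generations <- 0L
  for (s in seeds) {
    if (s$score < bestScore) { bestScore <- s$score; bestMembers <- s$members }
  }
  if (is.null(bestMembers)) bestMembers <- seeds[[1]]$members
  current <- seeds
  if (config$maxIterations > 1L) {
    for (it in seq_len(config$maxIterations - 1L)) {
      current <- growModels(current, network, x, survival, config)
      if (!length(current)) break
      generations <- generations + 1L
      for (mod in current) {
        if (mod$score < bestScore) {
          bestScore <- mod$score
          bestMembers <- mod$members
        }
      }
    }
  }
  ids <- sort(bestMembers)
  refit <- fitCox(x[, ids, drop = FALSE], survival)
  src <- if (is.null(featureSources)) rep(NA_character_, length(ids)) else
    unname(featureSources[ids])
  new("SurvivalModel", featureIds = ids, featureSources = src,
      beta = unname(coef(refit)), method = "NFS", fitness = bestScore,
      trainIds = patientIds(survival),
      meta = list(generations = generations, converged = refit@converged,
                  config = unclass(config)))
}

#' Expand a gene-level network to tagged merged features
#'
#' In the merged matrix, gene/protein connections apply irrespective of the
#' data type: an edge (g, h) links every feature whose base id is g to
#' every feature whose base id is h, and features sharing a base id are
#' linked to each other.
#'
#' @param network an \linkS4class{InteractionNetwork} over base ids (genes
#'   and, after \code{\link{buildSurrogateNetwork}}, miRNAs).
#' @param featureIds source-prefixed feature ids of the merged matrix.
#' @return An \linkS4class{InteractionNetwork} over the prefixed ids.
#' @export
expandNetworkToFeatures <- function(network, featureIds) {
  base <- baseFeatureId(featureIds)
  byBase <- split(featureIds, base)
  el <- igraph::as_edgelist(networkGraph(network))
  edges <- list()
  if (nrow(el)) {
    for (r in seq_len(nrow(el))) {
      a <- byBase[[el[r, 1]]]; b <- byBase[[el[r, 2]]]
      if (length(a) && length(b))
        edges[[length(edges) + 1L]] <- as.matrix(expand.grid(a, b,
          stringsAsFactors = FALSE))
    }
  }
  for (grp in byBase) {
    if (length(grp) > 1L) {
      cmb <- t(combn(grp, 2))
      edges[[length(edges) + 1L]] <- cmb
    }
  }
  em <- if (length(edges)) do.call(rbind, edges) else NULL
  InteractionNetwork(em, nodes = featureIds)
}
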