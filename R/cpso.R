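# Constrained particle swarm optimization over fixed-size feature subsets.
# Particles live in a continuous k-dimensional space over the feature-index
# range; positions decode to subsets by rounding with duplicate repair, and
# fitness is the mean bootstrap concordance of the decoded subset's Cox
# model.

#' Configuration for the swarm selector
#'
#' @param k features per model.
#' @param iterations swarm iterations per run.
#' @param runs independent swarm restarts; the best model across runs wins.
#'   The reference protocol used 1000 runs with 500 iterations; the desk
#'   default is 20 runs.
#' @param swarmSize particles per swarm.
#' @param inertia velocity inertia weight w.
#' @param cognitive personal-best acceleration c1.
#' @param social global-best acceleration c2.
#' @param vMax velocity clamp as a fraction of the feature-index range.
#' @param bootstrapB bootstrap replicates per fitness evaluation.
#' @param seed integer master seed.
#' @return A validated list of class \code{cpso_config}.
#' @export
cpsoConfig <- function(k = 5L, iterations = 500L, runs = 20L,
                       swarmSize = 30L, inertia = 0.72, cognitive = 1.49,
                       social = 1.49, vMax = 0.25, bootstrapB = 10L,
                       seed = 1L) {
  assertScalarCount(k, "k"); assertScalarCount(iterations, "iterations")
  assertScalarCount(runs, "runs"); assertScalarCount(swarmSize, "swarmSize")
  assertScalarCount(bootstrapB, "bootstrapB")
  assertFraction(vMax, "vMax")
  stopifnot(inertia >= 0, cognitive >= 0, social >= 0)
  structure(list(k = as.integer(k), iterations = as.integer(iterations),
                 runs = as.integer(runs), swarmSize = as.integer(swarmSize),
                 inertia = inertia, cognitive = cognitive, social = social,
                 vMax = vMax, bootstrapB = as.integer(bootstrapB),
                 seed = as.integer(seed)),
            class = "cpso_config")
}

#' Decode a particle position into a feature subset
#'
#' Rounds each coordinate to a 0-based feature index; duplicate indices are
#' repaired by advancing to the next unused index, wrapping at the end of
#' the feature range, so the decoded subset always has exactly \code{k}
#' distinct members.
#'
#' @param position numeric vector of k coordinates in
#'   \code{[0, featureCount - 1]}.
#' @param featureCount number of available features.
#' @return Integer vector of k distinct 0-based indices, in coordinate
#'   order.
#' @export
decodePosition <- function(position, featureCount) {
  featureCount <- as.integer(featureCount)
  k <- length(position)
  if (k > featureCount) stop("k exceeds the number of features")
  idx <- as.integer(round(pmin(pmax(position, 0), featureCount - 1)))
  used <- logical(featureCount)
  out <- integer(k)
  for (i in seq_len(k)) {
    j <- idx[i]
    while (used[j + 1L]) j <- (j + 1L) %% featureCount
    used[j + 1L] <- TRUE
    out[i] <- j
  }
  out
}

# deterministic fitness seed for a decoded subset: the same subset always
# gets the same bootstrap stream, so fitness is a pure function of the
# subset (and exhaustive search over subsets is well-defined)
subsetSeed <- function(seed, idx) {
  deriveSeed(seed, paste(sort(idx), collapse = ","))
}

#' One velocity/position update of a particle swarm
#'
#' Standard inertia-weight update: \code{v <- w v + c1 r1 (pbest - x) +
#' c2 r2 (gbest - x)} with per-dimension uniform r1, r2, velocity clamped
#' to \code{+/- vMax * range} and position clamped to the index range.
#' Personal and global bests update on strict fitness improvement.
#'
#' @param swarm list with matrices \code{position}, \code{velocity},
#'   \code{pbest} (all particles x k), vectors \code{pbestFit},
#'   \code{gbest} (length k), scalar \code{gbestFit}.
#' @param fitness fitness of each particle's current position.
#' @param config a \code{\link{cpsoConfig}}.
#' @param featureCount number of features (defines the coordinate range).
#' @return The updated swarm list.
#' @export
stepSwarm <- function(swarm, fitness, config, featureCount) {
  improved <- fitness > swarm$pbestFit
  swarm$pbest[improved, ] <- swarm$position[improved, , drop = FALSE]
  swarm$pbestFit[improved] <- fitness[improved]
  best <- which.max(swarm$pbestFit)
  if (swarm$pbestFit[best] > swarm$gbestFit) {
    swarm$gbest <- swarm$pbest[best, ]
    swarm$gbestFit <- swarm$pbestFit[best]
  }
  np <- nrow(swarm$position); k <- ncol(swarm$position)
  r1 <- matrix(runif(np * k), np, k)
  r2 <- matrix(runif(np * k), np, k)
  vlim <- config$vMax * (featureCount - 1)
  v <- config$inertia * swarm$velocity +
    config$cognitive * r1 * (swarm$pbest - swarm$position) +
    config$social * r2 * sweep(-swarm$position, 2, -swarm$gbest)
  v <- pmin(pmax(v, -vlim), vlim)
  x <- pmin(pmax(swarm$position + v, 0), featureCount - 1)
  swarm$velocity <- v
  swarm$position <- x
  swarm
}

initSwarm <- function(config, featureCount) {
  np <- config$swarmSize; k <- config$k
  vlim <- config$vMax * (featureCount - 1)
  list(position = matrix(runif(np * k, 0, featureCount - 1), np, k),
       velocity = matrix(runif(np * k, -vlim, vlim), np, k),
       pbest = matrix(NA_real_, np, k),
       pbestFit = rep(-Inf, np),
       gbest = rep(NA_real_, k),
       gbestFit = -Inf)
}

# fitness of a decoded subset with per-subset memoization
subsetFitness <- function(idx, x, survival, config, cache) {
  key <- paste(sort(idx), collapse = ",")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  sub <- x[, idx + 1L, drop = FALSE]
  fit <- tryCatch(
    suppressWarnings(bootstrapCindex(sub, survival, B = config$bootstrapB,
                                     seed = subsetSeed(config$seed, idx))),
    error = function(e) NA_real_)
  if (!is.finite(fit)) fit <- -Inf
  cache[[key]] <- fit
  fit
}

#' Run the constrained particle swarm feature selector
#'
#' Runs \code{runs} independent swarms over the feature-index space; each
#' particle's decoded k-subset is scored by mean bootstrap concordance of
#' its Cox model, and the best-scoring subset across all runs is refit once
#' on the full training data.
#'
#' @param x patients x features training matrix with feature ids as column
#'   names.
#' @param survival aligned \linkS4class{SurvivalData}.
#' @param config a \code{\link{cpsoConfig}}.
#' @param featureSources optional named source lookup for the features
#'   (defaults to \code{"EXPR"}-less empty tags).
#' @return A \linkS4class{SurvivalModel} with method \code{"CPSO"}; its
#'   fitness is the winning bootstrap c-index.
#' @export
runCpso <- function(x, survival, config = cpsoConfig(),
                    featureSources = NULL) {
  p <- ncol(x)
  if (config$k > p) stop("k exceeds the number of features")
  cache <- new.env(parent = emptyenv())
  bestFit <- -Inf; bestIdx <- NULL
  trace <- numeric(config$runs)
  for (r in seq_len(config$runs)) {
    withSeed(deriveSeed(config$seed, "cpso-run", r), {
      swarm <- initSwarm(config, p)
      for (it in seq_len(config$iterations)) {
        fitness <- vapply(seq_len(config$swarmSize), function(i) {
          idx <- decodePosition(swarm$position[i, ], p)
          subsetFitness(idx, x, survival, config, cache)
        }, numeric(1))
        swarm <- stepSwarm(swarm, fitness, config, p)
      }
      trace[r] <- swarm$gbestFit
      if (swarm$gbestFit > bestFit) {
        bestFit <- swarm$gbestFit
        bestIdx <- decodePosition(swarm$gbest, p)
      }
    })
  }
  if (is.null(bestIdx) || !is.finite(bestFit))
    stop("all swarm fitness evaluations failed")
  ids <- colnames(x)[bestIdx + 1L]
  refit <- fitCox(x[, ids, drop = FALSE], survival)
  src <- if (is.null(featureSources)) rep(NA_character_, length(ids)) else
    unname(featureSources[ids])
  new("SurvivalModel", featureIds = ids, featureSources = src,
      beta = unname(coef(refit)), method = "CPSO", fitness = bestFit,
      trainIds = patientIds(survival),
      meta = list(runFitness = trace, converged = refit@converged,
                  config = unclass(config)))
}
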