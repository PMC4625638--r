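# Synthetic multi-omic survival cohorts with planted prognostic structure.
# The generator emulates the shape of a TCGA-style cohort: continuous
# expression/miRNA/copy-number matrices and a sparse binary mutation matrix
# over a shared patient set, survival driven by a Cox linear predictor over
# planted features, exponential censoring calibrated to a target rate, and a
# preferential-attachment interaction network in which planted expression
# features form a connected subgraph.

#' Configuration for the synthetic cohort generator
#'
#' @param nPatients cohort size.
#' @param nFeatures named counts of features per source; names must be
#'   EXPR, MIRNA, CNA, MUT.
#' @param nPlanted named counts of prognostic (planted) features per source;
#'   each must not exceed the corresponding feature count.
#' @param effectSize Cox log-hazard coefficient per planted feature
#'   (unitless, applied to the standardized feature); either a single value
#'   recycled everywhere or a named list of per-source vectors.
#' @param censoringTarget desired fraction of censored patients, in [0, 1).
#' @param baselineScale Weibull scale of the baseline event-time
#'   distribution, in days.
#' @param weibullShape Weibull shape; 1 gives exponential event times.
#' @param mutationFrequencyRange range of per-gene mutation frequencies.
#' @param moduleSize number of features per correlated latent module in the
#'   continuous matrices (consecutive CNA features share a segment value).
#' @param moduleCor within-module correlation of the continuous sources.
#' @param networkDegreeParam preferential-attachment power of the synthetic
#'   interaction network.
#' @param hubDegree degree of one optional hub node wired into the network
#'   (0 = no hub); used to exercise hub exclusion in the network selector.
#' @param seed master seed; all randomness in the generator flows from it.
#' @return A validated list of class \code{synthetic_config}.
#' @export
syntheticConfig <- function(nPatients = 300L,
                            nFeatures = c(EXPR = 60L, MIRNA = 30L,
                                          CNA = 40L, MUT = 25L),
                            nPlanted = c(EXPR = 3L, MIRNA = 2L,
                                         CNA = 2L, MUT = 1L),
                            effectSize = 0.8,
                            censoringTarget = 0.3,
                            baselineScale = 730,
                            weibullShape = 1,
                            mutationFrequencyRange = c(0.05, 0.3),
                            moduleSize = 4L,
                            moduleCor = 0.75,
                            networkDegreeParam = 1,
                            hubDegree = 0L,
                            seed = 1L) {
  sources <- c("EXPR", "MIRNA", "CNA", "MUT")
  assertScalarCount(nPatients, "nPatients")
  if (!all(sources %in% names(nFeatures)))
    stop("nFeatures must be named with EXPR, MIRNA, CNA, MUT")
  nFeatures <- vapply(nFeatures[sources], assertScalarCount,
                      integer(1), name = "nFeatures")
  nPlanted <- vapply(sources, function(s) {
    k <- if (s %in% names(nPlanted)) nPlanted[[s]] else 0L
    k <- as.integer(k)
    if (is.na(k) || k < 0L) stop("nPlanted must be non-negative")
    if (k > nFeatures[[s]])
      stop("nPlanted exceeds nFeatures for source ", s)
    k
  }, integer(1))
  assertFraction(censoringTarget, "censoringTarget", lo = 0, lo_open = FALSE,
                 hi = 1, hi_open = TRUE)
  stopifnot(baselineScale > 0, weibullShape > 0, networkDegreeParam > 0,
            moduleSize >= 1, moduleCor >= 0, moduleCor < 1)
  if (length(mutationFrequencyRange) != 2L ||
      any(mutationFrequencyRange <= 0) || any(mutationFrequencyRange >= 1) ||
      mutationFrequencyRange[1] > mutationFrequencyRange[2])
    stop("mutationFrequencyRange must be increasing fractions in (0, 1)")
  if (is.numeric(effectSize) && length(effectSize) == 1L) {
    effectSize <- lapply(setNames(sources, sources),
                         function(s) rep(effectSize, nPlanted[[s]]))
  } else {
    effectSize <- lapply(setNames(sources, sources), function(s) {
      v <- effectSize[[s]]
      if (nPlanted[[s]] > 0L && length(v) != nPlanted[[s]])
        stop("effectSize for ", s, " must have length nPlanted")
      as.numeric(v)[seq_len(nPlanted[[s]])]
    })
  }
  structure(list(nPatients = as.integer(nPatients), nFeatures = nFeatures,
                 nPlanted = nPlanted, effectSize = effectSize,
                 censoringTarget = censoringTarget,
                 baselineScale = baselineScale, weibullShape = weibullShape,
                 mutationFrequencyRange = mutationFrequencyRange,
                 moduleSize = as.integer(moduleSize), moduleCor = moduleCor,
                 networkDegreeParam = networkDegreeParam,
                 hubDegree = as.integer(hubDegree), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Calibrate an exponential censoring rate to a target censoring fraction
#'
#' Given an event-time sample, finds by bisection the rate \eqn{\theta} of
#' an independent exponential censoring time such that the expected
#' censored fraction, \eqn{\mathrm{mean}(1 - e^{-\theta t_i})} over the
#' sample, equals the target.
#'
#' @param eventTimes positive event times.
#' @param target desired censoring fraction in [0, 1); 0 returns rate 0
#'   (censoring time = infinity, i.e. no censoring).
#' @return The calibrated exponential rate (per time unit).
#' @export
calibrateCensoring <- function(eventTimes, target) {
  if (any(eventTimes <= 0)) stop("event times must be positive")
  assertFraction(target, "target", lo = 0, lo_open = FALSE,
                 hi = 1, hi_open = TRUE)
  if (target == 0) return(0)
  frac <- function(theta) mean(1 - exp(-theta * eventTimes))
  lo <- 0; hi <- 1 / mean(eventTimes)
  while (frac(hi) < target) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (frac(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < 1e-12 * max(hi, 1)) break
  }
  (lo + hi) / 2
}

# continuous features x patients matrix built from latent modules of size
# `moduleSize` with within-module correlation `rho`; feature ids given.
# `sharedLatents` overrides the latent vector of the leading modules, so
# planted modules of different sources can load on the same prognostic
# factors (all data types reflect the same underlying biology).
latentModuleMatrix <- function(ids, n, moduleSize, rho, segment = FALSE,
                               sharedLatents = NULL) {
  p <- length(ids)
  nmod <- ceiling(p / moduleSize)
  module <- rep(seq_len(nmod), each = moduleSize)[seq_len(p)]
  latent <- matrix(rnorm(nmod * n), nmod, n)
  if (!is.null(sharedLatents) && nrow(sharedLatents) > 0L) {
    k <- min(nrow(sharedLatents), nmod)
    latent[seq_len(k), ] <- sharedLatents[seq_len(k), , drop = FALSE]
  }
  noise <- matrix(rnorm(p * n), p, n)
  v <- sqrt(rho) * latent[module, , drop = FALSE] + sqrt(1 - rho) * noise
  if (segment) {
    # copy-number style: shift whole segments by a shared baseline level
    level <- rnorm(nmod, 0, 0.5)
    v <- v + level[module]
  }
  dimnames(v) <- list(ids, paste0("P", seq_len(n)))
  v
}

#' Generate a synthetic multi-omic survival cohort
#'
#' Draws the four source matrices, plants prognostic features whose
#' standardized values drive a Weibull event-time model through a Cox
#' linear predictor, calibrates exponential censoring to the configured
#' target, and builds an interaction network (planted expression features
#' rewired into one connected component) plus a miRNA-to-gene target map in
#' which every planted miRNA targets at least one expression feature.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return List with elements \code{survival} (\linkS4class{SurvivalData}),
#'   \code{matrices} (named list of \linkS4class{OmicsMatrix}),
#'   \code{network} (\linkS4class{InteractionNetwork}), \code{mirnaTargets}
#'   (\linkS4class{MirnaTargetMap}) and \code{truth} (the planted-feature
#'   record: ids and coefficients per source, achieved censoring fraction,
#'   and the generator seed).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$nPatients
  pids <- sprintf("P%04d", seq_len(n))
  withSeed(config$seed, {
    ids <- list(
      EXPR = sprintf("GENE%04d", seq_len(config$nFeatures[["EXPR"]])),
      MIRNA = sprintf("MIR%04d", seq_len(config$nFeatures[["MIRNA"]])),
      CNA = sprintf("CNAREG%04d", seq_len(config$nFeatures[["CNA"]])),
      MUT = sprintf("MUTG%04d", seq_len(config$nFeatures[["MUT"]])))

    # shared prognostic factors: the j-th planted module of every source
    # loads on the same latent axis u_j, mimicking data types that all
    # reflect the same underlying tumor biology (copy-number dosage,
    # miRNA regulation of targets, downstream expression)
    maxPlanted <- max(config$nPlanted)
    shared <- if (maxPlanted > 0L)
      matrix(rnorm(maxPlanted * n), maxPlanted, n) else NULL
    latentsFor <- function(s) {
      k <- config$nPlanted[[s]]
      if (k == 0L || is.null(shared)) NULL
      else shared[seq_len(k), , drop = FALSE]
    }

    mats <- list()
    for (s in c("EXPR", "MIRNA")) {
      mats[[s]] <- latentModuleMatrix(ids[[s]], n, config$moduleSize,
                                      config$moduleCor,
                                      sharedLatents = latentsFor(s))
    }
    mats[["CNA"]] <- latentModuleMatrix(ids[["CNA"]], n, config$moduleSize,
                                        config$moduleCor, segment = TRUE,
                                        sharedLatents = latentsFor("CNA"))
    freq <- runif(config$nFeatures[["MUT"]],
                  config$mutationFrequencyRange[1],
                  config$mutationFrequencyRange[2])
    mut <- matrix(rbinom(config$nFeatures[["MUT"]] * n, 1L,
                         rep(freq, times = n)),
                  config$nFeatures[["MUT"]], n,
                  dimnames = list(ids[["MUT"]], pids))
    mats[["MUT"]] <- mut
    for (s in c("EXPR", "MIRNA", "CNA")) colnames(mats[[s]]) <- pids

    # planted features: first member of distinct latent modules, so each
    # planted feature keeps correlated partners (they must survive the
    # correlation filter downstream)
    planted <- lapply(setNames(names(ids), names(ids)), function(s) {
      k <- config$nPlanted[[s]]
      if (k == 0L) return(character())
      if (s == "MUT") return(ids[[s]][seq_len(k)])
      first_of_module <- seq(1L, length(ids[[s]]), by = config$moduleSize)
      ids[[s]][first_of_module[seq_len(min(k, length(first_of_module)))]]
    })
    # planted mutations get frequencies at the top of the range (so they
    # pass the frequency filter) and are enriched in patients high on the
    # shared prognostic factor
    if (length(planted$MUT)) {
      hi <- config$mutationFrequencyRange[2]
      for (j in seq_along(planted$MUT)) {
        pr <- plogis(qlogis(hi) + shared[j, ])
        mats$MUT[planted$MUT[j], ] <- rbinom(n, 1L, pr)
      }
    }

    # linear predictor over standardized planted features
    eta <- rep(0, n)
    for (s in names(planted)) {
      for (j in seq_along(planted[[s]])) {
        v <- mats[[s]][planted[[s]][j], ]
        sdv <- sd(v)
        z <- if (sdv > 0) (v - mean(v)) / sdv else rep(0, n)
        eta <- eta + config$effectSize[[s]][j] * z
      }
    }

    # Weibull event times with hazard proportional to exp(eta):
    # T = scale * (-log U / exp(eta))^(1/shape)
    u <- runif(n)
    etime <- config$baselineScale *
      (-log(u) / exp(eta))^(1 / config$weibullShape)
    etime <- pmax(etime, 1e-6)
    theta <- calibrateCensoring(etime, config$censoringTarget)
    if (theta > 0) {
      ctime <- rexp(n, rate = theta)
      time <- pmin(etime, ctime)
      event <- as.integer(etime <= ctime)
    } else {
      time <- etime
      event <- rep(1L, n)
    }
    surv <- SurvivalData(pids, time, event)

    # interaction network over EXPR ids: preferential attachment, planted
    # features rewired into one connected chain, optional hub
    g <- igraph::sample_pa(length(ids$EXPR), power = config$networkDegreeParam,
                           directed = FALSE)
    igraph::V(g)$name <- ids$EXPR
    if (length(planted$EXPR) > 1L) {
      chain <- cbind(planted$EXPR[-length(planted$EXPR)], planted$EXPR[-1])
      g <- igraph::add_edges(g, t(chain))
    }
    if (config$hubDegree > 0L) {
      others <- setdiff(ids$EXPR, planted$EXPR)
      hub <- others[1]
      tgt <- sample(setdiff(ids$EXPR, hub),
                    min(config$hubDegree, length(ids$EXPR) - 1L))
      g <- igraph::add_edges(g, rbind(hub, tgt))
    }
    g <- igraph::simplify(g)
    network <- new("InteractionNetwork", graph = g)

    # each miRNA targets 1-3 expression genes; planted miRNAs always get
    # at least one target by construction
    targets <- lapply(setNames(ids$MIRNA, ids$MIRNA), function(m)
      sample(ids$EXPR, sample(1:3, 1)))
    tmap <- MirnaTargetMap(targets)

    truth <- list(planted = planted,
                  coefficients = config$effectSize,
                  achievedCensoring = mean(event == 0L),
                  seed = config$seed)

    list(survival = surv,
         matrices = list(EXPR = OmicsMatrix(mats$EXPR, "EXPR"),
                         MIRNA = OmicsMatrix(mats$MIRNA, "MIRNA"),
                         CNA = OmicsMatrix(mats$CNA, "CNA"),
                         MUT = OmicsMatrix(mats$MUT, "MUT")),
         network = network, mirnaTargets = tmap, truth = truth)
  })
}

#' Write a generated cohort to a directory of TSV files
#'
#' Emits one matrix TSV per source (\code{expr.tsv}, \code{mirna.tsv},
#' \code{cna.tsv}, \code{mut.tsv}), the clinical table
#' (\code{clinical.tsv}), the network edge list (\code{network.tsv}), the
#' miRNA target links (\code{mirna_targets.tsv}) and the planted-feature
#' record as a flat key-value file (\code{truth.txt}).
#'
#' @param cohort output of \code{\link{generateCohort}}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
writeDataset <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expr = file.path(dir, "expr.tsv"),
             mirna = file.path(dir, "mirna.tsv"),
             cna = file.path(dir, "cna.tsv"),
             mut = file.path(dir, "mut.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             network = file.path(dir, "network.tsv"),
             targets = file.path(dir, "mirna_targets.tsv"),
             truth = file.path(dir, "truth.txt"))
  writeOmicsMatrix(cohort$matrices$EXPR, paths["expr"])
  writeOmicsMatrix(cohort$matrices$MIRNA, paths["mirna"])
  writeOmicsMatrix(cohort$matrices$CNA, paths["cna"])
  writeOmicsMatrix(cohort$matrices$MUT, paths["mut"])
  writeSurvivalData(cohort$survival, paths["clinical"])
  writeInteractionNetwork(cohort$network, paths["network"])
  writeMirnaTargets(cohort$mirnaTargets, paths["targets"])
  tr <- cohort$truth
  kv <- c(sprintf("seed\t%d", tr$seed),
          sprintf("achieved_censoring\t%.6f", tr$achievedCensoring),
          unlist(lapply(names(tr$planted), function(s) {
            if (!length(tr$planted[[s]])) return(character())
            sprintf("planted_%s\t%s\t%.6f", s, tr$planted[[s]],
                    tr$coefficients[[s]])
          })))
  writeLines(kv, paths["truth"])
  invisible(paths)
}

#' Read a cohort written by \code{writeDataset}
#'
#' @param dir directory containing the TSV files.
#' @return List with the same \code{survival}, \code{matrices},
#'   \code{network} and \code{mirnaTargets} elements as
#'   \code{\link{generateCohort}} (the truth record is not reloaded).
#' @export
readDataset <- function(dir) {
  list(survival = readSurvivalData(file.path(dir, "clinical.tsv")),
       matrices = list(
         EXPR = readOmicsMatrix(file.path(dir, "expr.tsv"), "EXPR"),
         MIRNA = readOmicsMatrix(file.path(dir, "mirna.tsv"), "MIRNA"),
         CNA = readOmicsMatrix(file.path(dir, "cna.tsv"), "CNA"),
         MUT = readOmicsMatrix(file.path(dir, "mut.tsv"), "MUT")),
       network = readInteractionNetwork(file.path(dir, "network.tsv")),
       mirnaTargets = readMirnaTargets(file.path(dir, "mirna_targets.tsv")))
}
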