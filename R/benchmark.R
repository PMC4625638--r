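# Orchestration of the full comparison design: data types x algorithms on
# one cohort, the shared evaluation protocol (blind test for the swarm and
# network selectors on non-mutation data, resubstitution for the penalized
# selector and for all mutation models), and the downstream aggregation
# (margin averages, source distribution of merged models, kappa agreement
# matrices, censoring-vs-agreement experiment).

benchmarkDatatypes <- c("EXPR", "MIRNA", "CNA", "MUT", "MERGE")
benchmarkAlgorithms <- c("CPSO", "NFS", "LASSO")

# evaluation mode of one grid cell
cellMode <- function(datatype, algorithm) {
  if (algorithm == "LASSO" || datatype == "MUT") "resubstitution"
  else "blind_test"
}

#' Run the data-type x algorithm benchmark grid on one cohort
#'
#' Aligns and quantile-normalizes the cohort, applies the per-source
#' filters, builds the merged metabase, draws one event-stratified 2/3 :
#' 1/3 train/test split shared by every cell, and fills each (data type,
#' algorithm) cell with a selected model and its evaluation. Swarm and
#' network models on non-mutation data are evaluated on the blind test
#' third; penalized models and all mutation models use resubstitution.
#' Cell-level failures are recorded as "no model generated", never abort
#' the grid.
#'
#' @param cohort list with \code{survival}, \code{matrices} (named EXPR,
#'   MIRNA, CNA, MUT), \code{network} and \code{mirnaTargets}, as produced
#'   by \code{\link{generateCohort}} or assembled from the readers.
#' @param filterCfg a \code{\link{filterConfig}}.
#' @param cpsoCfg,nfsCfg,lassoCfg selector configurations.
#' @param seed master seed: drives the split and is folded into every
#'   selector seed.
#' @param datatypes,algorithms subsets of the full design, for smaller
#'   runs.
#' @param normalize quantile-normalize EXPR and MIRNA first (default TRUE).
#' @return A \code{benchmark_result} list: \code{grid} (one row per cell:
#'   datatype, algorithm, mode, cIndex, logrankChi2, logrankP, tier,
#'   nFeatures, ok), \code{models}, \code{evals} (keyed
#'   \code{"datatype.algorithm"}), \code{split}, and the filtered matrices.
#' @export
runBenchmark <- function(cohort, filterCfg = filterConfig(),
                         cpsoCfg = cpsoConfig(), nfsCfg = nfsConfig(),
                         lassoCfg = lassoConfig(), seed = 1L,
                         datatypes = benchmarkDatatypes,
                         algorithms = benchmarkAlgorithms,
                         normalize = TRUE) {
  aligned <- alignCohort(cohort$matrices, cohort$survival)
  mats <- aligned$matrices
  surv <- aligned$survival
  if (normalize) {
    for (s in intersect(c("EXPR", "MIRNA"), names(mats)))
      mats[[s]] <- quantileNormalize(mats[[s]])
  }
  filtered <- lapply(setNames(names(mats), names(mats)), function(s)
    filterSource(mats[[s]], surv, filterCfg))
  filtered <- filtered[vapply(filtered, function(m)
    nrow(omicsValues(m)) > 0L, logical(1))]
  merged <- buildMetabase(filtered)
  split <- stratifiedSplit(surv, 2 / 3, seed = deriveSeed(seed, "split"))

  surrogate <- buildSurrogateNetwork(cohort$network, cohort$mirnaTargets)
  networkFor <- function(datatype, fids) {
    switch(datatype,
      EXPR = cohort$network,
      MIRNA = surrogate,
      MERGE = expandNetworkToFeatures(surrogate, fids),
      InteractionNetwork(NULL, nodes = fids))  # CNA/MUT ids are not genes
  }

  dataFor <- function(datatype) {
    if (datatype == "MERGE") merged else filtered[[datatype]]
  }

  models <- list(); evals <- list(); rows <- list()
  for (dt in datatypes) {
    om <- dataFor(dt)
    if (is.null(om) || nrow(omicsValues(om)) == 0L) next
    fsrc <- featureSources(om)
    for (alg in algorithms) {
      key <- paste(dt, alg, sep = ".")
      mode <- cellMode(dt, alg)
      trainIds <- if (mode == "blind_test") split$train
                  else patientIds(surv)
      evalIds <- if (mode == "blind_test") split$test
                 else trainIds
      xtr <- modelMatrix(om, patients = trainIds)
      xev <- modelMatrix(om, patients = evalIds)
      strain <- subsetSurvival(surv, trainIds)
      seval <- subsetSurvival(surv, evalIds)
      cellSeed <- deriveSeed(seed, dt, alg)
      model <- tryCatch(suppressWarnings(switch(alg,
        CPSO = {
          cfg <- cpsoCfg; cfg$seed <- cellSeed
          cfg$k <- min(cfg$k, ncol(xtr))
          runCpso(xtr, strain, cfg, featureSources = fsrc)
        },
        NFS = {
          cfg <- nfsCfg; cfg$seed <- cellSeed
          runNfs(xtr, strain, networkFor(dt, colnames(xtr)), cfg,
                 featureSources = fsrc)
        },
        LASSO = {
          cfg <- lassoCfg; cfg$seed <- cellSeed
          runLasso(xtr, strain, cfg, featureSources = fsrc)
        })), error = function(e) NULL)
      if (is.null(model)) {
        rows[[key]] <- data.frame(datatype = dt, algorithm = alg,
                                  mode = mode, cIndex = NA_real_,
                                  logrankChi2 = NA_real_,
                                  logrankP = NA_real_, tier = "none",
                                  nFeatures = 0L, ok = FALSE,
                                  stringsAsFactors = FALSE)
        next
      }
      ev <- tryCatch(evaluateModel(model, xev, seval, mode = mode),
                     error = function(e) NULL)
      models[[key]] <- model
      if (!is.null(ev)) evals[[key]] <- ev
      rows[[key]] <- data.frame(
        datatype = dt, algorithm = alg, mode = mode,
        cIndex = if (is.null(ev)) NA_real_ else ev@cIndex,
        logrankChi2 = if (is.null(ev)) NA_real_ else ev@logrankChi2,
        logrankP = if (is.null(ev)) NA_real_ else ev@logrankP,
        tier = if (is.null(ev)) "none" else ev@tier,
        nFeatures = length(featureIds(model)), ok = !is.null(ev),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(grid = do.call(rbind, c(rows, make.row.names = FALSE)),
                 models = models, evals = evals, split = split,
                 filtered = filtered, merged = merged, survival = surv,
                 seed = seed),
            class = "benchmark_result")
}

#' Render a benchmark grid as an integer c-index table with tier letters
#'
#' @param result a \code{benchmark_result} (or any data.frame with
#'   \code{datatype}, \code{algorithm}, \code{cIndex}, \code{tier}).
#' @return data.frame, one row per algorithm and one column per data type;
#'   cells are strings like \code{"66 (b)"}, \code{"-"} where no model was
#'   generated.
#' @export
benchmarkTable <- function(result) {
  grid <- if (inherits(result, "benchmark_result")) result$grid else result
  algs <- unique(grid$algorithm)
  dts <- unique(grid$datatype)
  out <- matrix("-", length(algs), length(dts),
                dimnames = list(algs, dts))
  for (i in seq_len(nrow(grid))) {
    r <- grid[i, ]
    if (is.finite(r$cIndex)) {
      cell <- sprintf("%d", roundHalfUp(100 * r$cIndex))
      if (r$tier != "none") cell <- paste0(cell, " (", r$tier, ")")
      out[r$algorithm, r$datatype] <- cell
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Margin averages of an integer c-index grid
#'
#' Arithmetic means of 0-100 c-index values over a margin, rounded half-up
#' to integers; missing cells ("no model generated") are excluded from
#' their margin.
#'
#' @param grid long data.frame with columns \code{cohort} (optional),
#'   \code{algorithm}, \code{datatype}, \code{cindex} on the 0-100 scale.
#' @return List of data.frames: \code{byCohortDatatype} (the per-cohort
#'   "Average" rows, when a cohort column is present), \code{byAlgorithm}
#'   (per algorithm x data type, pooling cohorts) and \code{byDatatype}
#'   (the overall "Average" row).
#' @export
aggregateAverages <- function(grid) {
  stopifnot(all(c("algorithm", "datatype", "cindex") %in% names(grid)))
  avg <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    roundHalfUp(mean(v))
  }
  out <- list()
  if ("cohort" %in% names(grid)) {
    out$byCohortDatatype <- aggregate(cindex ~ cohort + datatype,
                                      data = grid, FUN = avg,
                                      na.action = NULL)
  }
  out$byAlgorithm <- aggregate(cindex ~ algorithm + datatype, data = grid,
                               FUN = avg, na.action = NULL)
  out$byDatatype <- aggregate(cindex ~ datatype, data = grid, FUN = avg,
                              na.action = NULL)
  out
}

#' Source distribution of merged-model features
#'
#' Counts the selected features of MERGE-trained models by source and
#' reports totals plus integer-rounded percentage shares, per algorithm
#' and overall.
#'
#' @param models list of MERGE-trained \linkS4class{SurvivalModel}s, or a
#'   data.frame of per-model counts with columns \code{algorithm},
#'   \code{EXPR}, \code{MIRNA}, \code{CNA}, \code{MUT}.
#' @return List with \code{perModel} (counts per model),
#'   \code{byAlgorithm} (counts + percentage shares) and \code{overall}
#'   (pooled counts, total size, percentage shares).
#' @export
sourceDistribution <- function(models) {
  srcs <- c("EXPR", "MIRNA", "CNA", "MUT")
  if (is.data.frame(models)) {
    counts <- models
  } else {
    counts <- do.call(rbind, lapply(models, function(m) {
      fs <- featureSources(m)
      if (anyNA(fs)) stop("model has untagged features")
      row <- vapply(srcs, function(s) sum(fs == s), numeric(1))
      as.data.frame(as.list(row))
    }))
    counts$algorithm <- vapply(models, function(m) m@method, character(1))
  }
  stopifnot(all(srcs %in% names(counts)))
  shares <- function(df) {
    tot <- colSums(df[, srcs, drop = FALSE])
    size <- sum(tot)
    pct <- if (size > 0) roundHalfUp(100 * tot / size) else rep(NA_real_, 4)
    list(counts = tot, size = size, percent = setNames(pct, srcs))
  }
  byAlg <- lapply(split(counts, counts$algorithm), shares)
  list(perModel = counts, byAlgorithm = byAlg, overall = shares(counts))
}

#' Kappa agreement matrix across benchmark cells
#'
#' For every pair of populated grid cells, dichotomizes each model's
#' prognostic index at its median over the patients the two cells share
#' and computes Cohen's kappa of the resulting risk groups. Cells without
#' models are omitted.
#'
#' @param result a \code{benchmark_result}.
#' @return Symmetric numeric matrix (unit diagonal where defined) with
#'   rows/columns named \code{"datatype.algorithm"}.
#' @export
kappaMatrix <- function(result) {
  evals <- result$evals
  keys <- names(evals)
  k <- length(keys)
  out <- matrix(NA_real_, k, k, dimnames = list(keys, keys))
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      pi1 <- evals[[i]]@prognosticIndex
      pi2 <- evals[[j]]@prognosticIndex
      common <- intersect(names(pi1), names(pi2))
      if (length(common) < 2L) next
      a <- pi1[common] > median(pi1[common])
      b <- pi2[common] > median(pi2[common])
      kp <- tryCatch(suppressWarnings(cohenKappa(a, b)),
                     error = function(e) NA_real_)
      out[i, j] <- kp
      out[j, i] <- kp
    }
  }
  out
}

#' Censoring rate versus cross-data-type agreement
#'
#' Generates matched synthetic cohorts (identical planted structure and
#' matrices, only the censoring target differs), trains one model per
#' continuous data type at each censoring level, and summarizes the mean
#' Cohen's kappa between the risk groups of different data types. This
#' probes the observation that prognostic agreement between data types
#' degrades as censoring grows.
#'
#' @param censoringLevels censoring targets to compare.
#' @param nSeeds number of independent cohorts per level.
#' @param baseConfig a \code{\link{syntheticConfig}} template (its
#'   censoring target and seed are overridden).
#' @param lassoCfg selector configuration; the penalized selector is used
#'   because one model per (seed, level, source) must be fit.
#' @param sources data types compared (continuous sources).
#' @param seed master seed.
#' @return List with \code{summary} (data.frame: level, meanKappa, sd,
#'   nSeeds) and \code{perSeed} (seeds x levels matrix of mean cross-type
#'   kappa).
#' @export
censoringAgreementExperiment <- function(censoringLevels = c(0, 0.8),
                                         nSeeds = 20L,
                                         baseConfig = syntheticConfig(),
                                         lassoCfg = lassoConfig(nFolds = 5L,
                                                                targetSize = 5L),
                                         sources = c("EXPR", "MIRNA", "CNA"),
                                         seed = 1L) {
  assertScalarCount(nSeeds, "nSeeds")
  perSeed <- matrix(NA_real_, nSeeds, length(censoringLevels),
                    dimnames = list(NULL, as.character(censoringLevels)))
  for (s in seq_len(nSeeds)) {
    cohortSeed <- deriveSeed(seed, "censoring-exp", s)
    for (li in seq_along(censoringLevels)) {
      cfg <- baseConfig
      cfg$censoringTarget <- censoringLevels[li]
      cfg$seed <- cohortSeed
      cohort <- generateCohort(cfg)
      pis <- list()
      for (src in sources) {
        x <- modelMatrix(cohort$matrices[[src]])
        cfgL <- lassoCfg; cfgL$seed <- deriveSeed(cohortSeed, src)
        model <- tryCatch(suppressWarnings(
          runLasso(x, cohort$survival, cfgL)), error = function(e) NULL)
        if (!is.null(model))
          pis[[src]] <- prognosticIndex(model, x)
      }
      if (length(pis) < 2L) next
      kk <- c()
      nm <- names(pis)
      for (i in seq_along(nm)) for (j in seq_len(i - 1L)) {
        a <- pis[[i]] > median(pis[[i]])
        b <- pis[[j]] > median(pis[[j]])
        kk <- c(kk, suppressWarnings(cohenKappa(a, b)))
      }
      perSeed[s, li] <- mean(kk, na.rm = TRUE)
    }
  }
  summary <- data.frame(
    level = censoringLevels,
    meanKappa = colMeans(perSeed, na.rm = TRUE),
    sd = apply(perSeed, 2, sd, na.rm = TRUE),
    nSeeds = colSums(is.finite(perSeed)))
  list(summary = summary, perSeed = perSeed)
}
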