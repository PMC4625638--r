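# Planted-signal recovery experiment: the study-condition check that every
# selector, given a cohort with strong planted prognostic features, finds a
# model that (a) generalizes to a blind test third and (b) contains at
# least one planted feature.

#' Planted-feature recovery across selectors
#'
#' For each seed: generates a synthetic cohort, draws the event-stratified
#' 2/3 : 1/3 split, trains each selector on the training patients'
#' expression matrix, and records the blind-test c-index and whether the
#' model contains any planted expression feature.
#'
#' @param nSeeds number of independent cohorts.
#' @param baseConfig a \code{\link{syntheticConfig}} template (seed
#'   overridden per repetition).
#' @param cpsoCfg,nfsCfg,lassoCfg selector configurations.
#' @param methods subset of \code{c("CPSO", "NFS", "LASSO")}.
#' @param seed master seed.
#' @return data.frame with one row per (seed, method): \code{seed},
#'   \code{method}, \code{cIndex} (blind test), \code{plantedHit},
#'   \code{nFeatures}.
#' @export
recoveryExperiment <- function(nSeeds = 20L,
                               baseConfig = syntheticConfig(),
                               cpsoCfg = cpsoConfig(k = 3L,
                                                    iterations = 30L,
                                                    runs = 3L,
                                                    swarmSize = 12L,
                                                    bootstrapB = 5L),
                               nfsCfg = nfsConfig(maxIterations = 4L),
                               lassoCfg = lassoConfig(nFolds = 5L,
                                                      targetSize = 5L),
                               methods = c("CPSO", "NFS", "LASSO"),
                               seed = 1L) {
  assertScalarCount(nSeeds, "nSeeds")
  rows <- list()
  for (s in seq_len(nSeeds)) {
    cfg <- baseConfig
    cfg$seed <- deriveSeed(seed, "recovery", s)
    cohort <- generateCohort(cfg)
    planted <- cohort$truth$planted$EXPR
    split <- stratifiedSplit(cohort$survival, 2 / 3,
                             seed = deriveSeed(cfg$seed, "split"))
    om <- cohort$matrices$EXPR
    xtr <- modelMatrix(om, patients = split$train)
    xte <- modelMatrix(om, patients = split$test)
    strain <- subsetSurvival(cohort$survival, split$train)
    stest <- subsetSurvival(cohort$survival, split$test)
    for (m in methods) {
      cellSeed <- deriveSeed(cfg$seed, m)
      model <- tryCatch(suppressWarnings(switch(m,
        CPSO = { c2 <- cpsoCfg; c2$seed <- cellSeed
                 runCpso(xtr, strain, c2) },
        NFS = { c2 <- nfsCfg; c2$seed <- cellSeed
                runNfs(xtr, strain, cohort$network, c2) },
        LASSO = { c2 <- lassoCfg; c2$seed <- cellSeed
                  runLasso(xtr, strain, c2) })),
        error = function(e) NULL)
      ci <- NA_real_; hit <- NA; nf <- 0L
      if (!is.null(model)) {
        ci <- tryCatch(concordanceIndex(prognosticIndex(model, xte), stest),
                       error = function(e) NA_real_)
        hit <- any(featureIds(model) %in% planted)
        nf <- length(featureIds(model))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, method = m, cIndex = ci, plantedHit = hit,
        nFeatures = nf, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
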