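# Penalized Cox selection along an elastic-net regularization path
# (glmnet backend), with event-stratified cross-validation and a
# closest-to-target-size model choice (the protocol keeps "around 10"
# features).

#' Configuration for the penalized Cox selector
#'
#' @param nFolds cross-validation folds (default 10).
#' @param targetSize preferred number of active features (default 10).
#' @param enAlpha elastic-net mixing in (0, 1]; 1 = pure lasso.
#' @param nLambda length of the lambda grid.
#' @param lambdaMinRatio smallest lambda as a fraction of lambda_max.
#' @param seed integer seed (controls fold assignment).
#' @return A validated list of class \code{lasso_config}.
#' @export
lassoConfig <- function(nFolds = 10L, targetSize = 10L, enAlpha = 1,
                        nLambda = 100L, lambdaMinRatio = 0.01, seed = 1L) {
  assertScalarCount(nFolds, "nFolds"); assertScalarCount(targetSize,
                                                         "targetSize")
  if (nFolds < 2L) stop("nFolds must be >= 2")
  assertFraction(enAlpha, "enAlpha")
  assertScalarCount(nLambda, "nLambda")
  assertFraction(lambdaMinRatio, "lambdaMinRatio")
  structure(list(nFolds = as.integer(nFolds),
                 targetSize = as.integer(targetSize), enAlpha = enAlpha,
                 nLambda = as.integer(nLambda),
                 lambdaMinRatio = lambdaMinRatio, seed = as.integer(seed)),
            class = "lasso_config")
}

#' Elastic-net penalized Cox path
#'
#' Solves the penalized Cox partial likelihood over a log-spaced lambda
#' grid from lambda_max (empty active set) downwards. Covariates are
#' standardized internally; coefficients are returned on the original
#' scale.
#'
#' @param x patients x features matrix.
#' @param survival aligned \linkS4class{SurvivalData}.
#' @param config a \code{\link{lassoConfig}}.
#' @return List with \code{lambda}, \code{beta} (features x lambda sparse
#'   matrix), \code{activeSets} (list of feature-id vectors) and the
#'   underlying \code{glmnet} fit.
#' @export
penalizedPath <- function(x, survival, config = lassoConfig()) {
  if (sum(survEvent(survival)) < 1L) stop("no events")
  if (any(apply(x, 2, sd) == 0))
    stop("all-constant covariates are not allowed")
  y <- survival::Surv(survTime(survival), survEvent(survival))
  fit <- glmnet::glmnet(x, y, family = "cox", alpha = config$enAlpha,
                        nlambda = config$nLambda,
                        lambda.min.ratio = config$lambdaMinRatio,
                        standardize = TRUE)
  if (length(fit$lambda) < config$nLambda) {
    # glmnet stopped the path early; retry on the full explicit grid and
    # keep the longer of the two paths (the explicit grid can fail
    # numerically on near-saturated or low-event data)
    lmax <- max(fit$lambda)
    grid <- exp(seq(log(lmax), log(lmax * config$lambdaMinRatio),
                    length.out = config$nLambda))
    fit2 <- tryCatch(suppressWarnings(
      glmnet::glmnet(x, y, family = "cox", alpha = config$enAlpha,
                     lambda = grid, standardize = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit2) && length(fit2$lambda) > length(fit$lambda))
      fit <- fit2
  }
  beta <- fit$beta
  active <- lapply(seq_along(fit$lambda), function(j)
    rownames(beta)[beta[, j] != 0])
  list(lambda = fit$lambda, beta = beta, activeSets = active, fit = fit)
}

# event-stratified fold ids: folds preserve the event fraction within one
# event per fold
stratifiedFolds <- function(survival, nFolds, seed) {
  ev <- survEvent(survival)
  n <- length(ev)
  fold <- integer(n)
  withSeed(seed, {
    for (s in c(0L, 1L)) {
      idx <- which(ev == s)
      fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
  })
  fold
}

#' Cross-validated model choice along the penalized path
#'
#' Scores every lambda by mean cross-validated partial-likelihood deviance
#' over event-stratified folds, then picks the lambda whose active-set size
#' is closest to the target size; ties go to the better (lower) CV
#' deviance. The chosen feature set is refit unpenalized on the full data.
#'
#' @param path output of \code{\link{penalizedPath}}.
#' @param x patients x features matrix used for the path.
#' @param survival aligned \linkS4class{SurvivalData}.
#' @param config a \code{\link{lassoConfig}}.
#' @param featureSources optional named source lookup.
#' @return A \linkS4class{SurvivalModel} with method \code{"LASSO"} (its
#'   fitness is the CV deviance at the chosen lambda), or \code{NULL} when
#'   no lambda yields a non-empty active set ("no model generated").
#' @export
cvSelect <- function(path, x, survival, config = lassoConfig(),
                     featureSources = NULL) {
  sizes <- lengths(path$activeSets)
  if (all(sizes == 0L)) {
    warning("no lambda yields a non-empty model; no model generated")
    return(NULL)
  }
  y <- survival::Surv(survTime(survival), survEvent(survival))
  foldid <- stratifiedFolds(survival, config$nFolds, config$seed)
  cv <- tryCatch(suppressWarnings(
    glmnet::cv.glmnet(x, y, family = "cox", alpha = config$enAlpha,
                      lambda = path$lambda, foldid = foldid,
                      type.measure = "deviance", standardize = TRUE)),
    error = function(e) NULL)
  # align cv results to the path's lambda grid; a failed CV degrades to
  # size-only selection
  cvm <- if (is.null(cv)) rep(NA_real_, length(path$lambda))
         else cv$cvm[match(round(path$lambda, 10), round(cv$lambda, 10))]
  nonEmpty <- which(sizes > 0L)
  if (max(sizes) < config$targetSize &&
      config$targetSize > 0L)
    if (all(sizes < config$targetSize))
      warning("no active set reaches the target size; choosing the largest")
  gap <- abs(sizes[nonEmpty] - config$targetSize)
  cand <- nonEmpty[gap == min(gap)]
  best <- if (length(cand) > 1L) {
    cm <- cvm[cand]
    cm[!is.finite(cm)] <- Inf
    cand[which.min(cm)]
  } else cand
  ids <- path$activeSets[[best]]
  refit <- fitCox(x[, ids, drop = FALSE], survival)
  src <- if (is.null(featureSources)) rep(NA_character_, length(ids)) else
    unname(featureSources[ids])
  new("SurvivalModel", featureIds = ids, featureSources = src,
      beta = unname(coef(refit)), method = "LASSO",
      fitness = if (is.finite(cvm[best])) cvm[best] else NA_real_,
      trainIds = patientIds(survival),
      meta = list(lambda = path$lambda[best], activeSize = sizes[best],
                  converged = refit@converged, config = unclass(config)))
}

#' Run the penalized Cox selector end to end
#'
#' @inheritParams penalizedPath
#' @param featureSources optional named source lookup.
#' @return A \linkS4class{SurvivalModel} or \code{NULL} (no model
#'   generated).
#' @export
runLasso <- function(x, survival, config = lassoConfig(),
                     featureSources = NULL) {
  path <- penalizedPath(x, survival, config)
  cvSelect(path, x, survival, config, featureSources)
}
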