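#' Patients-by-features model matrix for a feature subset
#'
#' Convenience transpose/subset used by all selectors: survival model fits
#' take patients in rows.
#'
#' @param x an \linkS4class{OmicsMatrix}.
#' @param features feature ids to keep (default: all).
#' @param patients patient ids to keep (default: all).
#' @return Numeric matrix, patients x features.
#' @export
modelMatrix <- function(x, features = NULL, patients = NULL) {
  v <- omicsValues(x)
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(v))
    if (length(missing))
      stop("features not present in matrix: ",
           paste(head(missing, 5), collapse = ", "))
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(patients)) {
    missing <- setdiff(patients, colnames(v))
    if (length(missing))
      stop("patients not present in matrix: ",
           paste(head(missing, 5), collapse = ", "))
    v <- v[, patients, drop = FALSE]
  }
  t(v)
}

subsetSurvival <- function(survival, ids) {
  SurvivalData(ids, survTime(survival)[ids], survEvent(survival)[ids])
}

#' Fit a multivariate Cox proportional hazards model
#'
#' Maximizes the Efron-tie-corrected partial likelihood (damped Newton
#' iterations via \code{\link[survival]{coxph}}). Aliased (collinear)
#' covariates receive a zero coefficient and flip the convergence flag;
#' divergent fits (monotone likelihood / separation) are reported through
#' \code{converged = FALSE} rather than an error.
#'
#' @param x numeric matrix, patients x features, with column names; row
#'   order must match \code{survival}.
#' @param survival a \linkS4class{SurvivalData} over the same patients.
#' @return A \linkS4class{CoxFit}.
#' @export
fitCox <- function(x, survival) {
  x <- as.matrix(x)
  n_events <- sum(survEvent(survival))
  if (n_events < 1L) stop("cannot fit a Cox model with no events")
  if (nrow(x) != length(patientIds(survival)))
    stop("x rows must match survival patients")
  if (ncol(x) > nrow(x))
    warning("more features than patients; fit may be unstable")
  y <- survival::Surv(survTime(survival), survEvent(survival))
  ok <- TRUE
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph.fit(x, y, strata = NULL, offset = NULL, init = NULL,
                          control = survival::coxph.control(iter.max = 100,
                                                            eps = 1e-9),
                          weights = NULL, method = "efron",
                          rownames = NULL),
      warning = function(w) {
        ok <<- FALSE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(x)))
  if (is.null(fit)) {
    return(new("CoxFit", featureIds = ids, beta = rep(0, length(ids)),
               se = rep(NA_real_, length(ids)),
               loglik = c(NA_real_, NA_real_), converged = FALSE,
               nEvents = as.integer(n_events)))
  }
  beta <- unname(fit$coefficients)
  se <- sqrt(pmax(diag(as.matrix(fit$var)), 0))
  if (length(se) < length(beta)) se <- rep(NA_real_, length(beta))
  aliased <- !is.finite(beta)
  if (any(aliased)) {
    beta[aliased] <- 0
    se[aliased] <- NA_real_
    ok <- FALSE
  }
  if (any(abs(beta) > 50)) ok <- FALSE  # runaway coefficients = separation
  new("CoxFit", featureIds = ids, beta = beta, se = as.numeric(se),
      loglik = as.numeric(fit$loglik), converged = ok,
      nEvents = as.integer(n_events))
}

#' Wald p-values of a Cox fit
#'
#' @param fit a \linkS4class{CoxFit}.
#' @return Named vector of two-sided Wald p-values (NA where the standard
#'   error is unavailable).
#' @export
coxWaldP <- function(fit) {
  z <- fit@beta / fit@se
  setNames(2 * pnorm(-abs(z)), fit@featureIds)
}

#' Likelihood-ratio p-value of a Cox fit against the null model
#'
#' @param fit a \linkS4class{CoxFit}.
#' @return p-value of the LRT chi-square with df = number of covariates.
#' @export
coxLrtP <- function(fit) {
  if (anyNA(fit@loglik)) return(1)
  stat <- 2 * (fit@loglik[2] - fit@loglik[1])
  if (!is.finite(stat) || stat < 0) return(1)
  pchisq(stat, df = length(fit@featureIds), lower.tail = FALSE)
}

#' Per-patient prognostic index (Cox linear predictor)
#'
#' @param fit a \linkS4class{CoxFit} or \linkS4class{SurvivalModel}.
#' @param x patients x features matrix containing all of the fit's features.
#' @return Named numeric vector, one value per patient (beta . x).
#' @export
prognosticIndex <- function(fit, x) {
  b <- coef(fit)
  miss <- setdiff(names(b), colnames(x))
  if (length(miss))
    stop("features missing from x: ", paste(head(miss, 5), collapse = ", "))
  drop(x[, names(b), drop = FALSE] %*% b)
}

#' Harrell's concordance index
#'
#' Fraction of usable patient pairs in which the patient with the higher
#' prognostic index experiences the event sooner. A pair is usable when the
#' smaller of the two times is an event time and the times differ; tied
#' indices count 0.5.
#'
#' @param pi per-patient prognostic index (higher = higher risk).
#' @param survival a \linkS4class{SurvivalData} in the same patient order.
#' @return Concordance in [0, 1].
#' @export
concordanceIndex <- function(pi, survival) {
  t <- unname(survTime(survival)); e <- unname(survEvent(survival))
  pi <- as.numeric(pi)
  stopifnot(length(pi) == length(t))
  cindexCore(pi, t, e)
}

# pair enumeration over events: each usable pair (t_i < t_j, event at t_i)
# is visited exactly once through its event member
cindexCore <- function(pi, t, e) {
  num <- 0; den <- 0
  for (i in which(e == 1L)) {
    later <- t > t[i]
    nl <- sum(later)
    if (!nl) next
    den <- den + nl
    d <- pi[i] - pi[later]
    num <- num + sum(d > 0) + 0.5 * sum(d == 0)
  }
  if (den == 0) stop("no usable pairs (all observations censored)")
  num / den
}

tierFromP <- function(p) {
  if (!is.finite(p)) return("none")
  if (p < 0.001) "c" else if (p < 0.01) "b" else if (p < 0.05) "a" else "none"
}

#' Median-split log-rank test of a prognostic index
#'
#' Splits patients at the median prognostic index (index <= median = low
#' risk) and tests the two Kaplan-Meier curves with the 1-df log-rank test.
#' The significance tier follows the usual 0.05 / 0.01 / 0.001 ladder
#' ("a", "b", "c"; "none" otherwise).
#'
#' @param pi per-patient prognostic index.
#' @param survival a \linkS4class{SurvivalData} in the same patient order.
#' @return List with \code{chi2}, \code{p}, \code{tier} and the logical
#'   \code{highRisk} group assignment.
#' @export
logrankMedianSplit <- function(pi, survival) {
  pi <- as.numeric(pi)
  high <- pi > median(pi)
  if (!any(high) || all(high))
    stop("median split produced an empty risk group")
  sd <- survival::survdiff(
    survival::Surv(survTime(survival), survEvent(survival)) ~ high)
  chi2 <- unname(sd$chisq)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p, tier = tierFromP(p), highRisk = high)
}

#' Cohen's kappa for two binary risk classifications
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' \eqn{p_o} the observed agreement and \eqn{p_e} the agreement expected
#' from the marginal class frequencies.
#'
#' @param a,b equal-length binary (logical or 0/1) vectors.
#' @return Kappa in [-1, 1]; \code{NA} (with a warning) when both raters
#'   are constant so that chance agreement is 1.
#' @export
cohenKappa <- function(a, b) {
  a <- as.integer(as.logical(a)); b <- as.integer(as.logical(b))
  n <- length(a)
  stopifnot(length(b) == n, n >= 2)
  po <- mean(a == b)
  pa1 <- mean(a); pb1 <- mean(b)
  pe <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  if (pe >= 1) {
    warning("kappa undefined: both classifications are constant")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Event-stratified train/test split
#'
#' Within each event stratum (censored / event), assigns
#' \code{round(trainFraction * stratum size)} patients to the training set,
#' so the event fraction is preserved. Two thirds training and one third
#' blind test is the protocol used for the swarm and network selectors.
#'
#' @param survival a \linkS4class{SurvivalData}.
#' @param trainFraction fraction of each stratum used for training.
#' @param seed integer seed; the same seed always gives the same split.
#' @return List with character vectors \code{train} and \code{test}.
#' @export
stratifiedSplit <- function(survival, trainFraction = 2 / 3, seed = 1L) {
  assertFraction(trainFraction, "trainFraction", hi_open = TRUE)
  ev <- survEvent(survival)
  ids <- patientIds(survival)
  train <- character()
  withSeed(seed, {
    for (s in c(0L, 1L)) {
      stratum <- ids[ev == s]
      if (length(stratum) < 2L)
        stop("event stratum of size < 2; cannot split")
      k <- round(trainFraction * length(stratum))
      train <- c(train, sample(stratum, k))
    }
  })
  list(train = sort(train), test = sort(setdiff(ids, train)))
}

#' Event-stratified bootstrap resample
#'
#' Samples patients with replacement within each event stratum, preserving
#' both stratum sizes exactly, so every resample has the original event
#' count.
#'
#' @param survival a \linkS4class{SurvivalData}.
#' @param seed optional integer seed.
#' @return Character vector of resampled patient ids (with repeats), length
#'   equal to the cohort size.
#' @export
stratifiedBootstrap <- function(survival, seed = NULL) {
  ev <- survEvent(survival)
  ids <- patientIds(survival)
  draw <- function() {
    unlist(lapply(c(0L, 1L), function(s) {
      stratum <- ids[ev == s]
      if (!length(stratum)) return(character())
      sample(stratum, length(stratum), replace = TRUE)
    }), use.names = FALSE)
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

# Evaluate one feature subset on one bootstrap resample (integer row
# indices, possibly repeated). Returns NA on a failed fit.
bootstrapReplicate <- function(x, t, e, idx) {
  xs <- x[idx, , drop = FALSE]
  # standardize for numerical stability (separation-prone resamples);
  # the concordance of the linear predictor is scale-invariant
  sds <- apply(xs, 2, sd)
  keep <- sds > 0
  if (!any(keep)) return(NA_real_)
  xs <- scale(xs[, keep, drop = FALSE])
  ts <- t[idx]; es <- e[idx]
  y <- survival::Surv(ts, es)
  newton <- function(iter_max) tryCatch(suppressWarnings(
    survival::coxph.fit(xs, y, strata = NULL, offset = NULL, init = NULL,
                        control = survival::coxph.control(iter.max = iter_max),
                        weights = NULL, method = "efron", rownames = NULL)),
    error = function(e) NULL)
  beta <- NULL
  # monotone likelihoods (separation) overflow with long Newton runs;
  # an early-stopped iterate still ranks patients correctly
  for (im in c(100L, 15L, 5L)) {
    fit <- newton(im)
    if (!is.null(fit) && all(is.finite(fit$coefficients))) {
      beta <- unname(fit$coefficients)
      break
    }
  }
  if (is.null(beta)) return(NA_real_)
  pi <- drop(xs %*% beta)
  tryCatch(cindexCore(pi, ts, es), error = function(e) NA_real_)
}

#' Mean bootstrap concordance of a feature subset
#'
#' Fits the Cox model on each of \code{B} event-stratified bootstrap
#' resamples and averages the resulting concordance indices. This is the
#' fitness function of the swarm selector.
#'
#' @param x patients x features matrix (the candidate subset's columns).
#' @param survival a \linkS4class{SurvivalData}.
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @return Mean c-index over the successful replicates.
#' @export
bootstrapCindex <- function(x, survival, B = 10L, seed = 1L) {
  assertScalarCount(B, "B")
  t <- unname(survTime(survival)); e <- unname(survEvent(survival))
  strata <- list(which(e == 0L), which(e == 1L))
  strata <- strata[lengths(strata) > 0L]
  vals <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- unlist(lapply(strata, function(s)
        s[sample.int(length(s), length(s), replace = TRUE)]),
        use.names = FALSE)
      bootstrapReplicate(x, t, e, idx)
    }, numeric(1))
  })
  ok <- sum(is.finite(vals))
  if (ok < B / 2)
    stop("more than half of the bootstrap fits failed")
  if (ok < B)
    warning(sprintf("%d of %d bootstrap fits failed and were excluded",
                    B - ok, B))
  mean(vals[is.finite(vals)])
}

#' Evaluate a survival model on a patient set
#'
#' Computes the prognostic index, Harrell's c-index and the median-split
#' log-rank test on the given evaluation patients.
#'
#' @param model a \linkS4class{SurvivalModel} (or \linkS4class{CoxFit}).
#' @param x patients x features matrix covering the evaluation patients.
#' @param survival \linkS4class{SurvivalData} for the same patients.
#' @param mode \code{"blind_test"} or \code{"resubstitution"}.
#' @return An \linkS4class{EvalResult}.
#' @export
evaluateModel <- function(model, x, survival, mode = "blind_test") {
  pi <- prognosticIndex(model, x)
  ci <- concordanceIndex(pi, survival)
  lr <- tryCatch(logrankMedianSplit(pi, survival),
                 error = function(e) list(chi2 = NA_real_, p = NA_real_,
                                          tier = "none"))
  new("EvalResult", cIndex = ci, logrankChi2 = lr$chi2, logrankP = lr$p,
      tier = lr$tier,
      prognosticIndex = setNames(pi, patientIds(survival)), mode = mode)
}
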