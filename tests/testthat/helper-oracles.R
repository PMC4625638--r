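# Independent reference implementations used as oracles. These are written
# naively (loops, explicit risk sets) on purpose: they share no code with
# the package internals.

# Harrell c-index by literal pair enumeration
naiveCindex <- function(pi, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    a <- if (time[i] < time[j]) i else j
    b <- if (time[i] < time[j]) j else i
    if (event[a] != 1) next
    den <- den + 1
    if (pi[a] > pi[b]) num <- num + 1
    else if (pi[a] == pi[b]) num <- num + 0.5
  }
  if (den == 0) return(NA_real_)
  num / den
}

# two-group log-rank chi-square from explicit risk-set tables
naiveLogrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- group == unique(group)[1]
  obs_minus_exp <- 0; varsum <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g1)
    obs_minus_exp <- obs_minus_exp + d1 - d * n1 / n
    if (n > 1)
      varsum <- varsum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  obs_minus_exp^2 / varsum
}

# Efron-corrected Cox partial log-likelihood for a single covariate
efronLoglik <- function(beta, x, time, event) {
  ll <- 0
  for (tt in unique(time[event == 1])) {
    D <- which(time == tt & event == 1)
    R <- which(time >= tt)
    d <- length(D)
    sumR <- sum(exp(beta * x[R]))
    sumD <- sum(exp(beta * x[D]))
    ll <- ll + sum(beta * x[D])
    for (l in seq_len(d) - 1L)
      ll <- ll - log(sumR - (l / d) * sumD)
  }
  ll
}

# grid + golden-section maximization of the 1-covariate partial likelihood
gridSearchBeta <- function(x, time, event, lo = -8, hi = 8) {
  optimize(function(b) efronLoglik(b, x, time, event),
           interval = c(lo, hi), maximum = TRUE, tol = 1e-7)$maximum
}

# small random survival data set
randomSurvival <- function(n, seed, censor_frac = 0.3) {
  set.seed(seed)
  time <- round(rexp(n, 1 / 100), 3) + 0.001
  event <- as.integer(runif(n) > censor_frac)
  if (sum(event) == 0) event[1] <- 1L
  SurvivalData(sprintf("P%02d", seq_len(n)), time, event)
}

# toy omics matrix with explicit values
toyOmics <- function(values, source = "EXPR", features = NULL,
                     patients = NULL) {
  v <- as.matrix(values)
  if (is.null(features)) features <- sprintf("f%02d", seq_len(nrow(v)))
  if (is.null(patients)) patients <- sprintf("P%02d", seq_len(ncol(v)))
  dimnames(v) <- list(features, patients)
  OmicsMatrix(v, source)
}

smallConfig <- function(...) {
  args <- list(...)
  defaults <- list(nPatients = 80L,
                   nFeatures = c(EXPR = 16L, MIRNA = 8L, CNA = 8L,
                                 MUT = 6L),
                   nPlanted = c(EXPR = 2L, MIRNA = 1L, CNA = 1L, MUT = 1L),
                   seed = 1L)
  do.call(syntheticConfig, utils::modifyList(defaults, args))
}
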