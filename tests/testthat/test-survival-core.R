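test_that("fitCox agrees with direct partial-likelihood maximization", {
  # 8-patient toy data, one covariate
  time <- c(5, 8, 12, 16, 20, 30, 44, 60)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(0.6, -0.1, 0.8, 0.2, -0.5, 0.4, -0.9, -0.2)
  sv <- SurvivalData(paste0("P", 1:8), time, event)
  fit <- fitCox(matrix(x, 8, 1, dimnames = list(paste0("P", 1:8), "f")), sv)
  oracle <- gridSearchBeta(x, time, event)
  expect_lt(abs(unname(coef(fit)) - oracle), 1e-3)

  # a covariate independent of survival: beta ~ 0
  set.seed(3)
  n <- 400
  svn <- randomSurvival(n, 3)
  xn <- matrix(rnorm(n), n, 1,
               dimnames = list(patientIds(svn), "noise"))
  fn <- fitCox(xn, svn)
  expect_lt(abs(unname(coef(fn))), 3 * fn@se)

  # duplicated covariate: non-unique optimum is flagged
  xd <- cbind(a = x, b = x)
  rownames(xd) <- paste0("P", 1:8)
  fd <- suppressWarnings(fitCox(xd, sv))
  expect_false(fd@converged)

  expect_error(fitCox(xn, SurvivalData(patientIds(svn), svn@time,
                                       rep(0L, n))), "no events")
})

test_that("single-covariate fits match the grid-search oracle across instances", {
  for (s in 1:10) {
    set.seed(500 + s)
    n <- 15 + s
    time <- round(rexp(n, 1 / 50), 2) + 0.01
    event <- as.integer(runif(n) > 0.3)
    if (sum(event) < 2) event[1:2] <- 1L
    x <- rnorm(n)
    sv <- SurvivalData(paste0("P", 1:n), time, event)
    fit <- fitCox(matrix(x, n, 1, dimnames = list(paste0("P", 1:n), "f")), sv)
    if (!fit@converged) next
    expect_lt(abs(unname(coef(fit)) - gridSearchBeta(x, time, event)), 1e-3)
  }
})

test_that("prognostic index is the linear predictor", {
  sv <- randomSurvival(3, 1)
  x <- matrix(c(2, 0, 1, 3, 1, 0), 3, 2,
              dimnames = list(patientIds(sv), c("a", "b")))
  fit <- new("CoxFit", featureIds = c("a", "b"), beta = c(1, -1),
             se = c(NA_real_, NA_real_), loglik = c(0, 0),
             converged = TRUE, nEvents = 2L)
  expect_equal(unname(prognosticIndex(fit, x)), c(2 - 3, 0 - 1, 1 - 0))
  fit0 <- new("CoxFit", featureIds = c("a", "b"), beta = c(0, 0),
              se = c(NA_real_, NA_real_), loglik = c(0, 0),
              converged = TRUE, nEvents = 2L)
  expect_equal(unname(prognosticIndex(fit0, x)), c(0, 0, 0))
  expect_error(prognosticIndex(fit, x[, 1, drop = FALSE]), "missing")
})

test_that("concordance index matches pair enumeration and survival::concordance", {
  # perfect inverse ranking, no censoring
  sv <- SurvivalData(paste0("P", 1:5), c(1, 2, 3, 4, 5), rep(1L, 5))
  expect_equal(concordanceIndex(c(5, 4, 3, 2, 1), sv), 1.0)
  # all indices equal: every usable pair is a tie
  expect_equal(concordanceIndex(rep(0, 5), sv), 0.5)

  # 6 patients with mixed censoring: exhaustive 15-pair oracle
  t6 <- c(3, 5, 5, 9, 12, 15); e6 <- c(1L, 0L, 1L, 1L, 0L, 1L)
  sv6 <- SurvivalData(paste0("P", 1:6), t6, e6)
  pi6 <- c(2.2, 1.0, 1.8, -0.5, 0.4, -1.3)
  expect_equal(concordanceIndex(pi6, sv6), naiveCindex(pi6, t6, e6))

  # random instances vs both oracles (tie-free times)
  for (s in 1:25) {
    set.seed(600 + s)
    n <- sample(5:10, 1)
    t <- sample(seq(10, 500, by = 7), n)
    e <- as.integer(runif(n) > 0.35); if (sum(e) == 0) e[1] <- 1L
    p <- rnorm(n)
    sv <- SurvivalData(paste0("P", 1:n), t, e)
    mine <- concordanceIndex(p, sv)
    expect_equal(mine, naiveCindex(p, t, e))
    conc <- survival::concordance(survival::Surv(t, e) ~ p, reverse = TRUE)
    expect_equal(mine, unname(conc$concordance))
  }

  # antisymmetry without index ties
  set.seed(77)
  t <- sample(1:100, 8); e <- rep(1L, 8); p <- rnorm(8)
  sv <- SurvivalData(paste0("P", 1:8), t, e)
  expect_equal(concordanceIndex(p, sv), 1 - concordanceIndex(-p, sv))

  expect_error(concordanceIndex(rnorm(4),
    SurvivalData(paste0("P", 1:4), 1:4, rep(0L, 4))), "usable")
})

test_that("median-split log-rank matches a hand risk-set computation", {
  # identical groups: no separation at all
  sv <- SurvivalData(paste0("P", 1:6), c(5, 10, 15, 5, 10, 15),
                     c(1L, 1L, 0L, 1L, 1L, 0L))
  pi <- c(1, 1, 1, -1, -1, -1)
  lr <- logrankMedianSplit(pi, sv)
  expect_equal(lr$chi2, 0, tolerance = 1e-9)
  expect_equal(lr$tier, "none")

  # 10-patient toy vs naive observed-minus-expected statistic
  t10 <- c(4, 7, 9, 13, 18, 22, 26, 31, 37, 42)
  e10 <- c(1L, 1L, 0L, 1L, 1L, 1L, 0L, 1L, 1L, 1L)
  pi10 <- c(3, 2.5, 2, 1.5, 1, -1, -1.5, -2, -2.5, -3)
  sv10 <- SurvivalData(paste0("P", 1:10), t10, e10)
  lr10 <- logrankMedianSplit(pi10, sv10)
  expect_equal(lr10$chi2, naiveLogrank(t10, e10, pi10 > median(pi10)),
               tolerance = 1e-9)
  # chi2 invariant under group relabeling
  expect_equal(lr10$chi2, naiveLogrank(t10, e10, pi10 <= median(pi10)),
               tolerance = 1e-9)

  # significance tier ladder
  expect_equal(survomics:::tierFromP(0.0005), "c")
  expect_equal(survomics:::tierFromP(0.005), "b")
  expect_equal(survomics:::tierFromP(0.03), "a")
  expect_equal(survomics:::tierFromP(0.2), "none")
})

test_that("Cohen's kappa follows the chance-corrected agreement formula", {
  expect_equal(cohenKappa(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(cohenKappa(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1.0)
  # 2x2 table (4, 1, 1, 4): po = 0.8, pe = 0.5 -> kappa 0.6
  a <- c(rep(1, 4), 1, 0, rep(0, 4))
  b <- c(rep(1, 4), 0, 1, rep(0, 4))
  expect_equal(cohenKappa(a, b), 0.6)
  # symmetry
  set.seed(5)
  x <- rbinom(50, 1, 0.4); y <- rbinom(50, 1, 0.6)
  expect_equal(cohenKappa(x, y), cohenKappa(y, x))
  expect_equal(cohenKappa(x, x), 1.0)
  expect_warning(k <- cohenKappa(rep(1, 5), rep(1, 5)), "undefined")
  expect_true(is.na(k))
})

test_that("stratified split preserves the event fraction", {
  ev <- c(rep(0L, 90), rep(1L, 30))
  sv <- SurvivalData(sprintf("P%03d", 1:120), rep(100, 120) + 1:120, ev)
  sp <- stratifiedSplit(sv, 2 / 3, seed = 9)
  expect_length(sp$train, 80)
  expect_length(sp$test, 40)
  evs <- survEvent(sv)
  expect_equal(sum(evs[sp$train]), 20)
  expect_equal(sum(evs[sp$test]), 10)
  expect_setequal(c(sp$train, sp$test), patientIds(sv))
  # determinism
  expect_identical(stratifiedSplit(sv, 2 / 3, seed = 9), sp)
  # random configurations: train event fraction within one patient
  for (s in 1:10) {
    set.seed(700 + s)
    n <- sample(30:90, 1)
    ev2 <- as.integer(runif(n) < runif(1, 0.2, 0.7))
    if (sum(ev2) < 2) ev2[1:2] <- 1L
    if (sum(ev2 == 0) < 2) ev2[1:2] <- 0:1
    sv2 <- SurvivalData(sprintf("Q%03d", 1:n), 1:n + 0.5, ev2)
    sp2 <- stratifiedSplit(sv2, 2 / 3, seed = s)
    expect_equal(sum(survEvent(sv2)[sp2$train]),
                 round(2 / 3 * sum(ev2)), tolerance = 1)
  }
})

test_that("stratified bootstrap preserves stratum sizes and covers ~63%", {
  ev <- c(rep(0L, 150), rep(1L, 100))
  sv <- SurvivalData(sprintf("P%03d", 1:250), 1:250 + 0.5, ev)
  ids <- stratifiedBootstrap(sv, seed = 4)
  expect_length(ids, 250)
  expect_equal(sum(survEvent(sv)[ids]), 100)  # event count exact
  fracs <- replicate(30, length(unique(stratifiedBootstrap(sv))) / 250)
  expect_equal(mean(fracs), 1 - exp(-1), tolerance = 0.03)
})

test_that("bootstrap c-index is exact for a perfect predictor and stabilizes with B", {
  set.seed(8)
  n <- 60
  time <- sort(rexp(n, 1 / 100), decreasing = TRUE) + 0.01
  sv <- SurvivalData(sprintf("P%02d", 1:n), time, rep(1L, n))
  # index = -time ranks perfectly on any resample
  x <- matrix(-time, n, 1, dimnames = list(patientIds(sv), "risk"))
  expect_equal(bootstrapCindex(x, sv, B = 1, seed = 1), 1.0)
  expect_equal(bootstrapCindex(x, sv, B = 7, seed = 2), 1.0)

  # variance shrinks with B
  set.seed(9)
  xn <- matrix(rnorm(2 * n), n, 2, dimnames = list(patientIds(sv), c("a", "b")))
  xn[, 1] <- xn[, 1] - scale(time)[, 1] * 0.8
  v5 <- var(sapply(1:12, function(s) bootstrapCindex(xn, sv, B = 5, seed = s)))
  v50 <- var(sapply(1:12, function(s) bootstrapCindex(xn, sv, B = 50,
                                                      seed = 100 + s)))
  expect_lt(v50, v5)
})
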