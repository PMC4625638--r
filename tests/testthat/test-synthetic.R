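test_that("censoring calibration hits its target", {
  # no censoring requested: rate 0, every subject has an event
  expect_identical(calibrateCensoring(rexp(100) + 0.01, 0), 0)
  co <- generateCohort(smallConfig(censoringTarget = 0))
  expect_true(all(survEvent(co$survival) == 1L))

  # two identical exponential races censor half: calibrated rate ~ 1
  set.seed(11)
  rate <- calibrateCensoring(rexp(50000, 1), 0.5)
  expect_equal(rate, 1, tolerance = 0.05)

  # Monte-Carlo: arbitrary event-time sample, target 0.3
  set.seed(12)
  et <- rweibull(10000, shape = 1.4, scale = 300)
  theta <- calibrateCensoring(et, 0.3)
  cens <- mean(rexp(10000, theta) < et)
  expect_gt(cens, 0.28); expect_lt(cens, 0.32)

  expect_error(calibrateCensoring(rexp(10), 1), "fraction")
})

test_that("achieved censoring tracks the configured target", {
  co <- generateCohort(syntheticConfig(nPatients = 500,
                                       censoringTarget = 0.5, seed = 21))
  expect_equal(co$truth$achievedCensoring, 0.5, tolerance = 0.05)
  # convergence at large n
  big <- generateCohort(syntheticConfig(
    nPatients = 10000, censoringTarget = 0.4,
    nFeatures = c(EXPR = 8L, MIRNA = 4L, CNA = 4L, MUT = 4L),
    nPlanted = c(EXPR = 1L, MIRNA = 0L, CNA = 0L, MUT = 0L), seed = 22))
  expect_equal(big$truth$achievedCensoring, 0.4, tolerance = 0.02)
})

test_that("generated cohorts satisfy their structural contracts", {
  co <- generateCohort(smallConfig(seed = 3, hubDegree = 10L))
  # MUT strictly binary, frequencies inside the configured range
  mv <- omicsValues(co$matrices$MUT)
  expect_true(all(mv %in% c(0, 1)))
  band <- smallConfig()$mutationFrequencyRange
  expect_true(all(rowMeans(mv) >= band[1] - 0.12 &
                  rowMeans(mv) <= band[2] + 0.12))
  # planted ids are emitted features
  for (s in names(co$truth$planted))
    expect_true(all(co$truth$planted[[s]] %in%
                      featureIds(co$matrices[[s]])))
  # planted EXPR features form a connected subgraph of the network
  g <- networkGraph(co$network)
  sub <- igraph::induced_subgraph(g, co$truth$planted$EXPR)
  expect_true(igraph::is_connected(sub))
  # every planted miRNA targets at least one expression feature
  tmap <- mirnaTargets(co$mirnaTargets)
  for (m in co$truth$planted$MIRNA)
    expect_gt(length(intersect(tmap[[m]], featureIds(co$matrices$EXPR))), 0)
  # matrices share the survival table's patient ordering
  for (m in co$matrices)
    expect_identical(patientIds(m), patientIds(co$survival))
  # the hub exists
  expect_gte(max(networkDegree(co$network)), 10)

  expect_error(syntheticConfig(nPatients = 0), "positive")
  expect_error(syntheticConfig(nPlanted = c(EXPR = 99, MIRNA = 0, CNA = 0,
                                            MUT = 0)), "exceeds")
})

test_that("a cohort with nothing planted behaves as a null model", {
  co <- generateCohort(smallConfig(
    nPatients = 150L,
    nFeatures = c(EXPR = 120L, MIRNA = 4L, CNA = 4L, MUT = 4L),
    nPlanted = c(EXPR = 0L, MIRNA = 0L, CNA = 0L, MUT = 0L), seed = 31))
  expect_identical(lengths(co$truth$planted),
                   c(EXPR = 0L, MIRNA = 0L, CNA = 0L, MUT = 0L))
  x <- modelMatrix(co$matrices$EXPR)
  p <- univariateScreen(x, co$survival)
  # Wald p-values behave as null draws: ~5% below 0.05
  expect_lt(mean(p < 0.05), 0.12)
  expect_gt(mean(p < 0.5), 0.3)
})

test_that("true planted predictor beats a random feature set out of sample", {
  wins <- 0L; total <- 0L
  for (s in 1:20) {
    co <- generateCohort(smallConfig(
      nPatients = 120L, seed = 100 + s, effectSize = 1.0))
    split <- stratifiedSplit(co$survival, 2 / 3, seed = s)
    om <- co$matrices$EXPR
    planted <- co$truth$planted$EXPR
    others <- setdiff(featureIds(om), planted)
    set.seed(s)
    rand <- sample(others, length(planted))
    ctr <- subsetSurvival(co$survival, split$train)
    cte <- subsetSurvival(co$survival, split$test)
    ci <- function(feats) {
      fit <- fitCox(modelMatrix(om, feats, split$train), ctr)
      concordanceIndex(
        prognosticIndex(fit, modelMatrix(om, feats, split$test)), cte)
    }
    c_true <- ci(planted); c_rand <- ci(rand)
    total <- total + 1L
    if (c_true > c_rand) wins <- wins + 1L
  }
  expect_lt(binom.test(wins, total, alternative = "greater")$p.value, 0.05)
})

test_that("datasets round-trip through the writers and readers", {
  dir <- withr::local_tempdir()
  co <- generateCohort(smallConfig(nPatients = 10L, seed = 5))
  paths <- writeDataset(co, dir)
  # 4 matrix files + 1 clinical + 2 edge lists (+ the truth record)
  expect_length(setdiff(names(paths), "truth"), 7L)
  expect_true(all(file.exists(paths)))
  back <- readDataset(dir)
  for (s in names(co$matrices))
    expect_equal(omicsValues(back$matrices[[s]]),
                 omicsValues(co$matrices[[s]]), tolerance = 1e-9)
  expect_equal(survTime(back$survival), survTime(co$survival),
               tolerance = 1e-9)
  expect_identical(survEvent(back$survival), survEvent(co$survival))

  # an all-zero mutation matrix survives the round trip
  z <- co
  zv <- omicsValues(z$matrices$MUT) * 0
  z$matrices$MUT <- OmicsMatrix(zv, "MUT")
  writeDataset(z, dir)
  b2 <- readDataset(dir)
  expect_true(all(omicsValues(b2$matrices$MUT) == 0))
})
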