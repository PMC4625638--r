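fastBenchmark <- function(cohort, seed = 11, ...) {
  runBenchmark(cohort,
               cpsoCfg = cpsoConfig(k = 2, iterations = 10, runs = 1,
                                    swarmSize = 8, bootstrapB = 5),
               nfsCfg = nfsConfig(maxIterations = 3),
               lassoCfg = lassoConfig(nFolds = 4, targetSize = 3),
               seed = seed, ...)
}

test_that("margin averages reproduce the printed arithmetic", {
  expect_equal(survomics:::roundHalfUp(mean(c(66, 60, 68))), 65)
  expect_equal(survomics:::roundHalfUp(mean(c(74, 71, 72))), 72)
  grid <- referenceCindexGrid()
  avg <- aggregateAverages(grid)
  ovExpr <- subset(avg$byCohortDatatype, cohort == "OV" & datatype == "EXPR")
  expect_equal(ovExpr$cindex, 65)
  luadExpr <- subset(avg$byCohortDatatype,
                     cohort == "LUAD" & datatype == "EXPR")
  expect_equal(luadExpr$cindex, 72)
  # a single value is its own average
  one <- data.frame(algorithm = "CPSO", datatype = "EXPR", cindex = 66)
  expect_equal(aggregateAverages(one)$byDatatype$cindex, 66)
  # the missing cell (no model generated) is excluded from its margin:
  # OV MUT averages over the two populated cells only
  ovMut <- subset(avg$byCohortDatatype, cohort == "OV" & datatype == "MUT")
  expect_equal(ovMut$cindex, survomics:::roundHalfUp(mean(c(10, 11))))
})

test_that("source distribution pools merged-model compositions correctly", {
  ref <- referenceMergeModels()
  dist <- sourceDistribution(ref)
  expect_equal(dist$overall$size, 108)
  expect_equal(unname(dist$overall$percent),
               c(54, 6, 27, 14))  # EXPR, MIRNA, CNA, MUT shares
  expect_lte(abs(sum(dist$overall$percent) - 100), 2)
  # per-algorithm shares match the printed per-block rows
  expect_equal(unname(dist$byAlgorithm$CPSO$percent), c(51, 5, 28, 15))
  expect_equal(unname(dist$byAlgorithm$NFS$percent), c(42, 0, 54, 4))
  expect_equal(unname(dist$byAlgorithm$LASSO$percent), c(63, 9, 9, 19))

  # a model with all features from one source is 100% that source
  m <- new("SurvivalModel", featureIds = c("EXPR:a", "EXPR:b"),
           featureSources = c("EXPR", "EXPR"), beta = c(0.1, 0.2),
           method = "CPSO", fitness = 0.7, trainIds = "P1", meta = list())
  d1 <- sourceDistribution(list(m))
  expect_equal(unname(d1$overall$percent), c(100, 0, 0, 0))
})

test_that("the benchmark grid populates every cell with the right mode", {
  co <- generateCohort(smallConfig(nPatients = 90L, seed = 77,
                                   effectSize = 1.0))
  bm <- fastBenchmark(co)
  expect_equal(nrow(bm$grid), 15)
  # protocol: penalized and mutation cells use resubstitution
  expect_true(all(bm$grid$mode[bm$grid$algorithm == "LASSO"] ==
                    "resubstitution"))
  expect_true(all(bm$grid$mode[bm$grid$datatype == "MUT"] ==
                    "resubstitution"))
  expect_true(all(bm$grid$mode[bm$grid$datatype == "EXPR" &
                                 bm$grid$algorithm != "LASSO"] ==
                    "blind_test"))
  # stored models re-evaluate to exactly the reported c-index
  for (key in names(bm$models)) {
    row <- bm$grid[bm$grid$datatype == sub("\\..*", "", key) &
                     bm$grid$algorithm == sub(".*\\.", "", key), ]
    ev <- bm$evals[[key]]
    expect_equal(unname(row$cIndex), ev@cIndex)
    expect_identical(row$tier, ev@tier)
  }
  # single-cell run
  bm1 <- fastBenchmark(co, datatypes = "EXPR", algorithms = "NFS")
  expect_equal(nrow(bm1$grid), 1)

  # rendered table shows integer c-index with tier letters
  tab <- benchmarkTable(bm)
  expect_identical(rownames(tab), c("CPSO", "NFS", "LASSO"))
  expect_true(all(grepl("^[0-9]+( \\([abc]\\))?$|^-$",
                        unlist(tab))))
})

test_that("benchmark runs are reproducible under the master seed", {
  co <- generateCohort(smallConfig(nPatients = 80L, seed = 78,
                                   effectSize = 1.0))
  b1 <- fastBenchmark(co, seed = 5, datatypes = c("EXPR", "MUT"))
  b2 <- fastBenchmark(co, seed = 5, datatypes = c("EXPR", "MUT"))
  expect_identical(b1$grid, b2$grid)
  expect_identical(lapply(b1$models, featureIds),
                   lapply(b2$models, featureIds))
})

test_that("kappa matrices are symmetric with unit diagonal and a null of ~0", {
  co <- generateCohort(smallConfig(nPatients = 90L, seed = 79,
                                   effectSize = 1.0))
  bm <- fastBenchmark(co, datatypes = c("EXPR", "CNA"))
  km <- kappaMatrix(bm)
  expect_identical(km, t(km))
  d <- diag(km)
  expect_true(all(abs(d[is.finite(d)] - 1) < 1e-12))

  # two independent random indices at large n: kappa ~ 0
  set.seed(80)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(cohenKappa(a > median(a), b > median(b))), 0.1)
})
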