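test_that("miRNA surrogate network inherits target-gene edges", {
  ppi <- InteractionNetwork(rbind(c("A", "B"), c("A", "C")))
  tm <- MirnaTargetMap(list(mir1 = "A", mir2 = "Z"))
  sg <- buildSurrogateNetwork(ppi, tm)
  g <- networkGraph(sg)
  expect_true(igraph::are_adjacent(g, "mir1", "B"))
  expect_true(igraph::are_adjacent(g, "mir1", "C"))
  # gene-gene edges retained, no self loops
  expect_true(igraph::are_adjacent(g, "A", "B"))
  expect_equal(sum(igraph::which_loop(g)), 0)
  # a miRNA with no target in the graph is an isolated node
  expect_true("mir2" %in% igraph::V(g)$name)
  expect_equal(unname(networkDegree(sg, "mir2")), 0L)

  # toy graph + 2 miRNAs: full edge set equals the hand enumeration
  ppi2 <- InteractionNetwork(rbind(c("g1", "g2"), c("g2", "g3"),
                                   c("g3", "g4"), c("g4", "g5")))
  tm2 <- MirnaTargetMap(list(ma = "g2", mb = c("g4", "g5")))
  sg2 <- buildSurrogateNetwork(ppi2, tm2)
  got <- igraph::as_edgelist(networkGraph(sg2))
  got <- sort(apply(got, 1, function(r) paste(sort(r), collapse = "-")))
  want <- sort(c("g1-g2", "g2-g3", "g3-g4", "g4-g5",
                 "g1-ma", "g3-ma",              # ma inherits g2's partners
                 "g3-mb", "g5-mb", "g4-mb"))    # mb inherits g4's and g5's
  expect_identical(got, want)

  expect_error(buildSurrogateNetwork(ppi, MirnaTargetMap(list(A = "B"))),
               "disjoint")
})

test_that("univariate screen degrades failures to p = 1 and finds signal", {
  co <- generateCohort(smallConfig(nPatients = 120L, seed = 66,
                                   effectSize = 1.2))
  x <- modelMatrix(co$matrices$EXPR)
  p <- univariateScreen(x, co$survival)
  planted <- co$truth$planted$EXPR
  expect_lt(max(p[planted]), min(1, sort(p)[6]) + 1e-12)
  # constant covariate: no information
  xc <- cbind(x, flat = rep(2, nrow(x)))
  pc <- univariateScreen(xc, co$survival)
  expect_equal(unname(pc["flat"]), 1)
  # single-feature screen equals the fit's own Wald p
  f1 <- colnames(x)[1]
  fit <- fitCox(x[, f1, drop = FALSE], co$survival)
  expect_equal(unname(p[f1]), unname(coxWaldP(fit)))
})

test_that("model growth respects the network, hubs and the top-fraction cut", {
  # planted pair sits on a 6-node path; exhaustive search over the 5
  # connected pairs is the oracle
  set.seed(30)
  n <- 120
  ids <- paste0("n", 1:6)
  u <- rnorm(n)
  x <- sapply(1:6, function(i) rnorm(n, sd = 1))
  x[, 3] <- u + rnorm(n, sd = 0.5)
  x[, 4] <- u + rnorm(n, sd = 0.5)
  colnames(x) <- ids; rownames(x) <- sprintf("P%03d", 1:n)
  time <- rexp(n, exp(1.2 * u)) * 100 + 0.01
  sv <- SurvivalData(rownames(x), time, rep(1L, n))
  path <- InteractionNetwork(cbind(ids[1:5], ids[2:6]))

  seeds <- lapply(ids, function(f)
    list(members = f, score = survomics:::scoreModel(f, x, sv)))
  grown <- growModels(seeds, path, x, sv,
                      nfsConfig(topFraction = 1, maxIterations = 2))
  pairs <- cbind(ids[1:5], ids[2:6])
  oracleScores <- apply(pairs, 1, function(pr)
    survomics:::scoreModel(pr, x, sv))
  best <- sort(pairs[which.min(oracleScores), ])
  # the best grown 2-model equals the exhaustive connected-pair oracle
  expect_identical(sort(grown[[1]]$members), best)
  expect_equal(grown[[1]]$score, min(oracleScores))
  # and the full run surfaces it (or a strictly better-scoring model)
  model <- runNfs(x, sv, path, nfsConfig(topFraction = 1,
                                         maxIterations = 2))
  expect_lte(model@fitness, min(oracleScores))

  # an edgeless network returns the best single-feature model
  lone <- InteractionNetwork(NULL, nodes = ids)
  m0 <- runNfs(x, sv, lone, nfsConfig(maxIterations = 5))
  seedScores <- vapply(ids, function(f)
    survomics:::scoreModel(f, x, sv), numeric(1))
  expect_identical(featureIds(m0), names(which.min(seedScores)))

  # maxIterations = 1: no growth allowed
  m1 <- runNfs(x, sv, path, nfsConfig(maxIterations = 1))
  expect_length(featureIds(m1), 1)

  # a hub neighbor above the degree limit is never added
  star <- InteractionNetwork(cbind("n3", ids[-3]))
  grown <- growModels(list(list(members = "n1", score = 0.5)), star, x, sv,
                      nfsConfig(topFraction = 1, hubDegreeLimit = 3))
  expect_length(grown, 0)  # n1's only neighbor is the excluded hub (deg 5)
  ok <- growModels(list(list(members = "n1", score = 0.5)), star, x, sv,
                   nfsConfig(topFraction = 1, hubDegreeLimit = 5))
  expect_length(ok, 1)     # raising the limit admits it again
  expect_setequal(ok[[1]]$members, c("n1", "n3"))
})

test_that("the returned model is connected and selection improves the score", {
  co <- generateCohort(smallConfig(nPatients = 120L, seed = 67,
                                   effectSize = 1.0))
  x <- modelMatrix(co$matrices$EXPR)
  model <- runNfs(x, co$survival, co$network, nfsConfig(maxIterations = 4))
  ids <- featureIds(model)
  if (length(ids) > 1) {
    sub <- igraph::induced_subgraph(networkGraph(co$network), ids)
    expect_true(igraph::is_connected(sub))
  }
  # the final score is at least as good as the best single-feature seed
  seedScores <- vapply(colnames(x), function(f)
    survomics:::scoreModel(f, x, co$survival), numeric(1))
  expect_lte(model@fitness, min(seedScores) + 1e-12)
  # terminates within the iteration cap
  expect_lte(model@meta$generations, 3)
})
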