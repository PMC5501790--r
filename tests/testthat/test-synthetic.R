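test_that("planted correlation reproduces the simple closed-form cases", {
  pair <- cohortSpec(nSubjects = 1, nTimepoints = 10, modules = list(m = 1:2),
                     topology = "pair", rWithin = 0.8, rBetween = 0,
                     subjectNoiseSd = 0, seed = 1)
  expect_equal(plantedCorrelation(pair),
               matrix(c(1, .8, .8, 1), 2), tolerance = 1e-12)

  degenerate <- cohortSpec(nSubjects = 1, nTimepoints = 10,
                           modules = list(m = 1:2, n = 3:4),
                           topology = "pair", rWithin = 0, rBetween = 0,
                           subjectNoiseSd = 0, seed = 1)
  expect_equal(plantedCorrelation(degenerate), diag(4), tolerance = 1e-12)
})

test_that("planted chain matrices are PSD with decaying off-chain entries", {
  spec <- cohortSpec(nSubjects = 1, nTimepoints = 20, modules = list(m = 1:4),
                     topology = "chain", rWithin = 0.6, rBetween = 0.1,
                     subjectNoiseSd = 0, seed = 1)
  p <- plantedCorrelation(spec)
  expect_equal(max(abs(p - t(p))), 0)
  expect_equal(unname(diag(p)), rep(1, 4))
  expect_gte(min(eigen(p, symmetric = TRUE)$values), -1e-10)
  adj <- plantedAdjacency(spec)
  nonAdjacent <- p[upper.tri(p)][!adj[upper.tri(adj)]]
  expect_lt(max(nonAdjacent), 0.6)
})

test_that("PSD repair clips negative eigenvalues and renormalizes the diagonal", {
  # indefinite symmetric unit-diagonal matrix: 1s off-diagonal pattern
  # violating transitivity
  a <- matrix(c(1, .9, -.9,
                .9, 1, .9,
                -.9, .9, 1), 3, 3)
  expect_lt(min(eigen(a, symmetric = TRUE)$values), 0)
  rep <- NetScaffold:::.psdRepair(a)
  b <- rep$matrix
  expect_gte(min(eigen(b, symmetric = TRUE)$values), -1e-10)
  expect_equal(unname(diag(b)), rep(1, 3))
  expect_equal(max(abs(b - a)), rep$maxChange)
  expect_gt(rep$maxChange, 0)
})

test_that("planted adjacency marks exactly the topology edges", {
  spec <- tinyCohortSpec()
  adj <- plantedAdjacency(spec)
  expect_true(isSymmetric(adj))
  # chain 1-2-3-4: 3 edges; star hub 5 with leaves 6,7,8: 3 edges; pair: 1
  expect_identical(sum(adj) / 2, 7)
  expect_true(adj[1, 2] && adj[2, 3] && adj[3, 4] && !adj[1, 3])
  expect_true(adj[5, 6] && adj[5, 7] && adj[5, 8] && !adj[6, 7])
  expect_true(adj[9, 10])
})

test_that("increasing rWithin never decreases adjacent planted entries", {
  base <- tinyCohortSpec()
  adj <- plantedAdjacency(base)
  prev <- plantedCorrelation(base)
  for (rw in c(0.65, 0.7, 0.8)) {
    spec <- cohortSpec(nSubjects = 5, nTimepoints = 120,
                       modules = base@modules, topology = base@topology,
                       rWithin = rw, rBetween = 0.1, subjectNoiseSd = 0.1,
                       seed = 11)
    cur <- plantedCorrelation(spec)
    expect_true(all(cur[adj] >= prev[adj] - 1e-9))
    prev <- cur
  }
})

test_that("cohorts are deterministic under a fixed seed and independent across subjects", {
  spec <- tinyCohortSpec(seed = 21)
  c1 <- generateCohort(spec)
  c2 <- generateCohort(spec)
  expect_identical(lapply(c1, timeSeriesValues), lapply(c2, timeSeriesValues))
  # different subjects get different noise realizations
  expect_false(identical(timeSeriesValues(c1[[1]]), timeSeriesValues(c1[[2]])))
  # changing the master seed changes the data
  c3 <- generateCohort(tinyCohortSpec(seed = 22))
  expect_false(identical(timeSeriesValues(c1[[1]]), timeSeriesValues(c3[[1]])))
})

test_that("noiseless subject correlations converge to the planted matrix", {
  spec <- cohortSpec(nSubjects = 1, nTimepoints = 20000,
                     modules = list(m = 1:4, p = 5:6),
                     topology = c("chain", "pair"), rWithin = 0.6,
                     rBetween = 0.1, subjectNoiseSd = 0, seed = 5)
  planted <- plantedCorrelation(spec)
  ts <- generateCohort(spec)[[1]]
  expect_lt(max(abs(pearsonMatrix(ts) - planted)), 0.03)
})

test_that("cohort spec validation catches bad partitions and levels", {
  expect_error(cohortSpec(nSubjects = 2, nTimepoints = 50,
                          modules = list(a = 1:3, b = 3:5),
                          topology = "chain"),
               "partition")
  expect_error(cohortSpec(nSubjects = 2, nTimepoints = 50,
                          modules = list(a = 1:4), topology = "chain",
                          rWithin = 0.3, rBetween = 0.5),
               "rBetween")
  expect_warning(cohortSpec(nSubjects = 2, nTimepoints = 5,
                            modules = list(a = 1:8), topology = "chain"),
                 "rank deficient")
})
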