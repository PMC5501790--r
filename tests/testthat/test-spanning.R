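test_that("row-max forest of the 4-node example pairs up reciprocally", {
  w <- fourNodeExample()
  f <- msfRowMax(w)
  expect_equal(unname(f@arcs[, 2]), c(2L, 1L, 4L, 3L))
  expect_equal(length(unique(f@membership)), 2)
  expect_equal(nrow(f@reciprocated), 2)
  expect_equal(unname(f@arcWeights), c(.9, .9, .8, .8))

  # reciprocated-pair count identity: N - number of undirected edges
  und <- unique(cbind(pmin(f@arcs[, 1], f@arcs[, 2]),
                      pmax(f@arcs[, 1], f@arcs[, 2])))
  expect_equal(nrow(f@reciprocated), 4L - nrow(und))

  # N = 2: a single reciprocated pair
  f2 <- msfRowMax(matrix(c(0, .5, .5, 0), 2))
  expect_equal(nrow(f2@reciprocated), 1)
})

test_that("greedy list descent reproduces the hand traces", {
  w <- fourNodeExample()
  g <- msfGreedy(w)
  expect_equal(g$i, c(1, 3))
  expect_equal(g$j, c(2, 4))

  # path a-b-c-d with weights ab=3 > bc=2 > cd=1: greedy keeps all three
  wp <- matrix(0, 4, 4)
  wp[1, 2] <- wp[2, 1] <- 3
  wp[2, 3] <- wp[3, 2] <- 2
  wp[3, 4] <- wp[4, 3] <- 1
  gp <- msfGreedy(wp)
  expect_equal(gp[, c("i", "j")],
               data.frame(i = c(1, 2, 3), j = c(2, 3, 4)))
})

test_that("row-max and greedy forests agree on distinct weights", {
  set.seed(17)
  for (rep in 1:25) {
    w <- randomWeightMatrix(sample(4:12, 1))
    f <- msfRowMax(w)
    undF <- unique(cbind(pmin(f@arcs[, 1], f@arcs[, 2]),
                         pmax(f@arcs[, 1], f@arcs[, 2])))
    undF <- undF[order(undF[, 1], undF[, 2]), , drop = FALSE]
    g <- msfGreedy(w)
    undG <- as.matrix(g[, c("i", "j")])
    undG <- undG[order(undG[, 1], undG[, 2]), , drop = FALSE]
    expect_equal(unname(undF), unname(undG))
  }
})

test_that("forest completion yields the classical maximum spanning tree", {
  w <- fourNodeExample()
  f <- msfRowMax(w)
  tr <- mstComplete(f, w)
  expect_equal(nrow(tr@edges), 3)
  added <- tr@edges[tr@edgeWeights == .4, , drop = FALSE]
  expect_equal(sort(unname(added[1, ])), c(2, 3))
  expect_equal(tr@totalWeight, 2.1, tolerance = 1e-12)

  set.seed(23)
  for (rep in 1:20) {
    w <- randomWeightMatrix(10)
    tr <- mstComplete(msfRowMax(w), w)
    expect_equal(tr@totalWeight, igraphMaxSpanningWeight(w),
                 tolerance = 1e-12)
  }
})

test_that("planted chains are recovered as path components", {
  spec <- cohortSpec(nSubjects = 1, nTimepoints = 50,
                     modules = list(m = 1:6, p = 7:8),
                     topology = c("chain", "pair"), rWithin = 0.7,
                     rBetween = 0.05, subjectNoiseSd = 0, seed = 2)
  p <- plantedCorrelation(spec)
  f <- msfRowMax(p^2 - diag(diag(p^2)))
  # the chain module forms one component whose undirected support is the path
  expect_equal(f@membership[1:6], rep(f@membership[1], 6))
  prof <- degreeProfiles(f)
  expect_equal(prof@chainScore, 1)
  expect_true(all(plantedAdjacency(spec)[f@arcs]))
})

test_that("degree profiles count in-degrees, hubs and chain scores", {
  # size-2 reciprocated pair: in-degrees {1, 1}
  f2 <- msfRowMax(matrix(c(0, .5, .5, 0), 2))
  p2 <- degreeProfiles(f2)
  expect_equal(p2@degrees, c(1L, 1L))
  expect_equal(p2@chainScore, 1)

  # star: all leaves point to the hub; the hub reciprocates its strongest
  # leaf, which therefore has in-degree 1 while the other leaves have 0
  ws <- matrix(.01, 5, 5)
  ws[1, 2:5] <- ws[2:5, 1] <- c(.9, .8, .7, .6)
  diag(ws) <- 0
  fs <- msfRowMax(ws)
  ps <- degreeProfiles(fs)
  expect_equal(ps@degrees, c(4L, 1L, 0L, 0L, 0L))
  expect_equal(ps@maxDegree, 4L)
  expect_equal(unname(ps@histogram), c(3L, 1L, 1L))
  expect_equal(sum(ps@fractions), 1)
  expect_equal(ps@chainScore, (5 - 1) / 5)   # hub has undirected degree 4

  # pure path on 5 nodes has chain score 1 in the tree profile
  wp <- matrix(0, 5, 5)
  for (i in 1:4) wp[i, i + 1] <- wp[i + 1, i] <- .9 - .1 * i
  tp <- degreeProfiles(mstComplete(msfRowMax(wp), wp))
  expect_equal(tp@chainScore, 1)
  expect_equal(tp@maxDegree, 2L)
})

test_that("component summaries expose sizes, pairs and group labels", {
  w <- fourNodeExample()
  f <- msfRowMax(w, labels = c("L1", "R1", "L2", "R2"))
  cs <- componentSummary(f)
  expect_equal(nrow(cs), 2)
  expect_equal(sort(cs$size), c(2, 2))
  expect_true(all(cs$reciprocated))
  expect_equal(cs$chain_score, c(1, 1))

  groups <- c(L1 = "left", R1 = "right", L2 = "left", R2 = "right")
  cs2 <- componentSummary(f, groups)
  expect_true(all(grepl("left;right|right;left", cs2$groups)))

  # no label map: group column empty, no error
  expect_equal(componentSummary(f)$groups, c("", ""))
})

test_that("all-equal rows warn but still assign an arc by the tie rule", {
  w <- matrix(1, 3, 3); diag(w) <- 0
  warns <- capture_warnings(f <- msfRowMax(w))
  expect_length(warns, 3)
  expect_match(warns, "tie rule", all = TRUE)
  expect_equal(unname(f@arcs[, 2]), c(2L, 1L, 1L))
})
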