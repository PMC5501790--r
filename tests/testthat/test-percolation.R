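test_that("edges are ranked increasing with lexicographic tie-break", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- .1   # ab
  w[1, 3] <- w[3, 1] <- .8   # ac
  w[2, 3] <- w[3, 2] <- .8   # bc
  e <- rankEdges(w)
  expect_equal(e$weight, c(.1, .8, .8))
  expect_equal(e$i, c(1, 1, 2))
  expect_equal(e$j, c(2, 3, 3))

  # all-equal weights: pure lexicographic order
  w2 <- matrix(1, 4, 4); diag(w2) <- 0
  e2 <- rankEdges(w2)
  expect_equal(e2$i, c(1, 1, 1, 2, 2, 3))
  expect_equal(e2$j, c(2, 3, 4, 3, 4, 4))

  # N(N-1)/2 edges listed once
  expect_equal(nrow(rankEdges(randomWeightMatrix(20))), 190)
})

test_that("percolation of the weighted triangle follows the hand enumeration", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- .9
  w[2, 3] <- w[3, 2] <- .8
  w[1, 3] <- w[3, 1] <- .1
  cur <- percolate(w)
  # removing ac leaves the path a-b-c connected; removing bc isolates c;
  # removing ab isolates everyone
  expect_equal(cur@nComponents, c(1L, 2L, 3L))
  expect_equal(cur@weights, c(.1, .8, .9))
  expect_equal(cur@newborn, c(FALSE, TRUE, TRUE))
  expect_equal(cur@initialComponents, 1L)

  pl <- plateauLengths(cur)
  expect_equal(pl@lengths, c(.8 - .1, .9 - .8), tolerance = 1e-12)
  expect_equal(pl@startWeights, c(.1, .8))
  expect_equal(pl@endWeights, c(.8, .9))
})

test_that("edgeless and complete graphs hit the curve invariants", {
  cur <- percolate(matrix(0, 4, 4) + diag(0, 4) * 0)
  # all-zero weights: 6 zero-weight links still removed one at a time
  expect_equal(length(cur@weights), 6)
  expect_equal(cur@nComponents[6], 4L)
  expect_equal(length(plateauLengths(cur)@lengths),
               4L - cur@initialComponents)

  w <- randomWeightMatrix(9)
  cur2 <- percolate(w)
  expect_equal(tail(cur2@nComponents, 1), 9L)
  expect_false(is.unsorted(cur2@nComponents))
  # telescoping: plateau lengths sum to last newborn weight - min weight
  pl <- plateauLengths(cur2)
  expect_equal(sum(pl@lengths),
               max(cur2@weights[cur2@newborn]) - min(cur2@weights),
               tolerance = 1e-12)
})

test_that("component counts match brute-force flood fill on random graphs", {
  set.seed(31)
  for (n in c(5, 9, 14)) {
    w <- randomWeightMatrix(n)
    # make some ties to exercise the tie-break path
    w[w < .2] <- 0
    cur <- percolate(w)
    expect_equal(cur@nComponents, bruteComponentCounts(w))
  }
})

test_that("snapshots are dual to the percolation state", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- .9
  w[2, 3] <- w[3, 2] <- .8
  w[1, 3] <- w[3, 1] <- .1
  g <- snapshotGraph(w, .8)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::components(g)$no, 1)
  expect_equal(igraph::vcount(snapshotGraph(w, 1.5)), 3)
  expect_equal(igraph::ecount(snapshotGraph(w, 1.5)), 0)
  expect_equal(igraph::ecount(snapshotGraph(w, 0)), 3)

  # duality on a random graph: component partition at threshold t equals
  # the percolation state just before the first removal of weight >= t
  set.seed(5)
  wr <- randomWeightMatrix(12)
  cur <- percolate(wr)
  for (t in c(.2, .5, .9)) {
    snap <- igraph::components(snapshotGraph(wr, t))$no
    k <- which(cur@weights >= t)[1]   # first removal with weight >= t
    stateBefore <- if (k == 1) cur@initialComponents else
      cur@nComponents[k - 1]
    expect_equal(snap, stateBefore)
  }
})

test_that("threshold selection separates real plateaux from null bands", {
  mkPlateaus <- function(lens, starts = cumsum(c(0, head(lens, -1)))) {
    new("PlateauSet", lengths = lens, startWeights = starts,
        endWeights = starts + lens)
  }
  real <- mkPlateaus(c(.01, .4, .02))
  nullsZero <- list(mkPlateaus(c(0, 0, 0)), mkPlateaus(c(0, 0, 0)))
  # null plateaux all zero: every positive real plateau selected
  selAll <- selectThresholds(real, nullsZero)
  expect_length(selAll, 3)
  expect_equal(as.numeric(selAll), sort(real@startWeights, decreasing = TRUE))

  # real lengths all below the band: empty selection
  nulls <- replicate(6, mkPlateaus(c(.05, .45, .05)), simplify = FALSE)
  selNone <- selectThresholds(real, nulls)
  expect_length(selNone, 0)

  # matched comparison flags the one transition that deviates
  selOne <- selectThresholds(mkPlateaus(c(.05, .9, .05)), nulls)
  expect_length(selOne, 1)
  expect_equal(as.numeric(selOne), .05)  # start of the second plateau

  # pooled comparison uses one global cutoff
  selPooled <- selectThresholds(mkPlateaus(c(.05, .9, .05)), nulls,
                                comparison = "pooled")
  pool <- rep(c(.05, .45, .05), 6)
  expect_equal(attr(selPooled, "cutoff"),
               rep(mean(pool) + 4 * sd(pool), 3), tolerance = 1e-12)

  expect_error(selectThresholds(real, nullsZero[1]), "nullPlateaus")
})
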