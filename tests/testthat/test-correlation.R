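test_that("pearsonMatrix matches the textbook covariance formula", {
  x <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
  r <- pearsonMatrix(x)
  expect_equal(r["a", "b"], -1)
  expect_equal(unname(diag(r)), c(1, 1))

  set.seed(42)
  v <- matrix(rnorm(200), 50, 4)
  r <- pearsonMatrix(v)
  # direct oracle: cov / (sd_i sd_j), entry by entry
  oracle <- matrix(1, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    cij <- mean((v[, i] - mean(v[, i])) * (v[, j] - mean(v[, j]))) *
      50 / 49
    oracle[i, j] <- oracle[j, i] <- cij / (sd(v[, i]) * sd(v[, j]))
  }
  expect_equal(unname(r), oracle, tolerance = 1e-12)

  v[, 2] <- 7
  colnames(v) <- paste0("ROI", 1:4)
  expect_error(pearsonMatrix(v), "ROI2")
})

test_that("fisherAverage applies tanh-mean-atanh entrywise", {
  m1 <- matrix(c(1, .2, .2, 1), 2)
  m2 <- matrix(c(1, .8, .8, 1), 2)
  stack <- new("CorrelationStack", matrices = list(m1, m2),
               roiLabels = c("A", "B"))
  g <- fisherAverage(stack)
  expect_equal(groupR(g)[1, 2], tanh((atanh(.2) + atanh(.8)) / 2),
               tolerance = 1e-12)
  expect_equal(groupW(g)[1, 2], groupR(g)[1, 2]^2, tolerance = 1e-12)
  expect_equal(unname(diag(groupW(g))), c(0, 0))

  # fixed point: identical subjects
  stackSame <- new("CorrelationStack", matrices = list(m1, m1, m1),
                   roiLabels = c("A", "B"))
  expect_equal(groupR(fisherAverage(stackSame)), m1, tolerance = 1e-12)

  # antisymmetry: +a and -a average to zero
  m3 <- matrix(c(1, -.8, -.8, 1), 2)
  stackAnti <- new("CorrelationStack", matrices = list(m2, m3),
                   roiLabels = c("A", "B"))
  expect_equal(groupR(fisherAverage(stackAnti))[1, 2], 0, tolerance = 1e-12)
})

test_that("fisherAverage commutes with subject permutation and stays in z-range", {
  set.seed(7)
  mats <- replicate(5, randomCorrelationMatrix(6), simplify = FALSE)
  labels <- paste0("ROI", 1:6)
  g1 <- fisherAverage(new("CorrelationStack", matrices = mats,
                          roiLabels = labels))
  g2 <- fisherAverage(new("CorrelationStack", matrices = rev(mats),
                          roiLabels = labels))
  expect_equal(groupR(g1), groupR(g2), tolerance = 1e-12)
  # group r lies between the min and max subject values (monotone tanh of
  # a mean of z-values)
  arr <- simplify2array(mats)
  lo <- apply(arr, c(1, 2), min)
  hi <- apply(arr, c(1, 2), max)
  expect_true(all(groupR(g1) >= lo - 1e-12 & groupR(g1) <= hi + 1e-12))
})

test_that("variability maps use arithmetic mean, ddof-1 SD and an FDR CV mask", {
  m1 <- matrix(c(1, .2, .2, 1), 2)
  m2 <- matrix(c(1, .8, .8, 1), 2)
  stack <- new("CorrelationStack", matrices = list(m1, m2, m1, m2),
               roiLabels = c("A", "B"))
  vm <- variabilityMaps(stack)
  expect_equal(vm@mean[1, 2], 0.5)            # arithmetic, not Fisher
  expect_equal(vm@sd[1, 2], sd(c(.2, .8, .2, .8)), tolerance = 1e-12)
  expect_equal(sd(c(.2, .8)), sqrt(2 * 0.09), tolerance = 1e-12)

  # identical subjects: sd 0, cv 0 on retained edges
  stackSame <- new("CorrelationStack", matrices = list(m2, m2, m2),
                   roiLabels = c("A", "B"))
  vmSame <- variabilityMaps(stackSame)
  expect_equal(vmSame@sd[1, 2], 0)
  expect_true(vmSame@fdrMask[1, 2])
  expect_equal(vmSame@cv[1, 2], 0)

  # balanced +/- values: mean 0, FDR drops the edge, cv undefined
  m3 <- matrix(c(1, -.2, -.2, 1), 2)
  stackBal <- new("CorrelationStack",
                  matrices = list(m1, m3, m1, m3, m1, m3),
                  roiLabels = c("A", "B"))
  vmBal <- variabilityMaps(stackBal)
  expect_equal(vmBal@mean[1, 2], 0)
  expect_false(vmBal@fdrMask[1, 2])
  expect_true(is.na(vmBal@cv[1, 2]))

  expect_error(variabilityMaps(stack, fdrQ = 1.2), "fdrQ")
})

test_that("cosine similarity works on strict upper triangles", {
  a <- matrix(c(1, .6, .6, 1), 2)
  b <- matrix(c(1, .3, .3, 1), 2)
  expect_equal(cosineSimilarity(a, a), 1)
  expect_equal(cosineSimilarity(a, b), 1)  # 1-dim vectors, same sign
  x <- diag(3); x[1, 2] <- x[2, 1] <- .5
  y <- diag(3); y[1, 3] <- y[3, 1] <- .5
  expect_equal(cosineSimilarity(x, y), 0)
  expect_error(cosineSimilarity(diag(3), diag(3)), "zero-norm")
})

test_that("jackknife similarity matches brute-force leave-one-out", {
  set.seed(9)
  mats <- replicate(3, randomCorrelationMatrix(5), simplify = FALSE)
  stack <- new("CorrelationStack", matrices = mats,
               roiLabels = paste0("R", 1:5))
  sim <- jackknifeSimilarity(stack)
  # brute force: recompute each leave-one-out group matrix directly
  loo <- lapply(1:3, function(k) {
    z <- Reduce(`+`, lapply(mats[-k], function(m)
      atanh(pmin(pmax(m, -1 + 1e-12), 1 - 1e-12))))
    tanh(z / 2)
  })
  for (i in 1:2) for (j in (i + 1):3) {
    ui <- loo[[i]][upper.tri(loo[[i]])]
    uj <- loo[[j]][upper.tri(loo[[j]])]
    expect_equal(sim[i, j], sum(ui * uj) / sqrt(sum(ui^2) * sum(uj^2)),
                 tolerance = 1e-12)
  }
  expect_equal(attr(sim, "minOffDiag"), min(sim[upper.tri(sim)]))

  # identical subjects: all leave-one-out averages coincide
  stackSame <- new("CorrelationStack", matrices = mats[c(1, 1, 1)],
                   roiLabels = paste0("R", 1:5))
  simSame <- jackknifeSimilarity(stackSame)
  expect_equal(unname(simSame), matrix(1, 3, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})
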