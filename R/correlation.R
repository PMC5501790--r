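.clipR <- function(r, eps = 1e-12) pmin(pmax(r, -1 + eps), 1 - eps)

#' Pearson correlation matrix of one subject
#'
#' @param ts a [SubjectTimeSeries-class] (or a plain T x N matrix) with at
#'   least 3 time points and no constant column.
#' @return N x N symmetric Pearson correlation matrix with unit diagonal.
#' @export
pearsonMatrix <- function(ts) {
  v <- if (is(ts, "SubjectTimeSeries")) ts@values else as.matrix(ts)
  if (nrow(v) < 3L) stop("need at least 3 time points", call. = FALSE)
  vars <- apply(v, 2L, stats::var)
  if (any(vars == 0)) {
    bad <- colnames(v)[vars == 0]
    if (is.null(bad)) bad <- which(vars == 0)
    stop("constant ROI signal (zero variance): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- cor(v)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Build a correlation stack from a cohort
#'
#' @param cohort list of [SubjectTimeSeries-class] with matching ROIs.
#' @return a [CorrelationStack-class].
#' @export
correlationStack <- function(cohort) {
  stopifnot(length(cohort) >= 1L)
  mats <- lapply(cohort, pearsonMatrix)
  labels <- colnames(if (is(cohort[[1L]], "SubjectTimeSeries"))
    cohort[[1L]]@values else cohort[[1L]])
  if (is.null(labels)) labels <- paste0("ROI", seq_len(nrow(mats[[1L]])))
  new("CorrelationStack", matrices = mats, roiLabels = labels)
}

#' Fisher-averaged group correlation matrix
#'
#' Subject matrices are Fisher-transformed (atanh), averaged entrywise
#' across subjects, and back-transformed (tanh). Correlations are clipped
#' to |r| <= 1 - 1e-12 before atanh. The companion weight matrix is
#' `w = r^2` with a zero diagonal; it is the input to the percolation and
#' spanning-structure stages.
#'
#' @param stack a [CorrelationStack-class] with at least one subject.
#' @return a [GroupMatrix-class].
#' @export
fisherAverage <- function(stack) {
  stopifnot(is(stack, "CorrelationStack"))
  if (!nSubjects(stack)) stop("empty correlation stack", call. = FALSE)
  zsum <- Reduce(`+`, lapply(stack@matrices, function(m) atanh(.clipR(m))))
  r <- tanh(zsum / nSubjects(stack))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  w <- r^2
  diag(w) <- 0
  new("GroupMatrix", r = r, w = w, roiLabels = stack@roiLabels)
}

#' Inter-subject variability maps
#'
#' Entrywise mean and sample standard deviation (denominator n-1) of the
#' raw correlation values across subjects, and their coefficient of
#' variation sd/|mean|. The CV is only reported on edges whose Fisher-z
#' values differ significantly from zero across subjects (one-sample
#' t-test, Benjamini-Hochberg FDR at level `fdrQ` over all N(N-1)/2
#' edges); elsewhere it is `NA`. Edges with near-zero mean correlation
#' have unstable CVs, and those are exactly the edges the FDR mask drops.
#'
#' @param stack a [CorrelationStack-class] with at least 3 subjects.
#' @param fdrQ FDR level in (0, 1); default 0.05.
#' @return a [VariabilityMaps-class].
#' @export
variabilityMaps <- function(stack, fdrQ = 0.05) {
  stopifnot(is(stack, "CorrelationStack"))
  if (fdrQ <= 0 || fdrQ >= 1) stop("fdrQ must be in (0, 1)", call. = FALSE)
  ns <- nSubjects(stack)
  if (ns < 3L) stop("need at least 3 subjects for variability maps",
                    call. = FALSE)
  n <- nRois(stack)
  arr <- array(unlist(stack@matrices), dim = c(n, n, ns))
  mu <- apply(arr, c(1L, 2L), mean)
  sdm <- apply(arr, c(1L, 2L), sd)

  zarr <- atanh(.clipR(arr))
  zm <- apply(zarr, c(1L, 2L), mean)
  zs <- apply(zarr, c(1L, 2L), sd)
  tstat <- zm / (zs / sqrt(ns))
  tstat[zs == 0 & zm != 0] <- Inf
  tstat[zs == 0 & zm == 0] <- 0
  p <- 2 * pt(abs(tstat), df = ns - 1L, lower.tail = FALSE)

  ut <- upper.tri(p)
  padj <- p
  padj[ut] <- p.adjust(p[ut], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  mask <- padj <= fdrQ
  diag(mask) <- FALSE

  cv <- matrix(NA_real_, n, n)
  cv[mask] <- sdm[mask] / abs(mu[mask])
  new("VariabilityMaps", mean = mu, sd = sdm, cv = cv,
      fdrMask = mask, fdrQ = fdrQ)
}

#' Cosine similarity between two correlation matrices
#'
#' Cosine of the angle between the vectorized strict upper triangles
#' (diagonal excluded, since the constant unit diagonal would inflate
#' similarity).
#'
#' @param a,b matrices of identical shape.
#' @return a scalar in \[-1, 1\].
#' @export
cosineSimilarity <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  x <- a[upper.tri(a)]
  y <- b[upper.tri(b)]
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("zero-norm upper triangle: cosine similarity undefined",
         call. = FALSE)
  sum(x * y) / (nx * ny)
}

#' Jackknife similarity of leave-one-out group matrices
#'
#' For each subject k, the group matrix is recomputed with subject k
#' removed (Fisher averaging of the remaining subjects); the pairwise
#' cosine similarities between the leave-one-out group matrices quantify
#' how much any single subject drives the group average. Values near 1 on
#' every off-diagonal entry mean no subject is influential.
#'
#' @param stack a [CorrelationStack-class] with at least 3 subjects.
#' @return an n x n similarity matrix with attributes `minOffDiag` and
#'   `maxOffDiag`.
#' @export
jackknifeSimilarity <- function(stack) {
  stopifnot(is(stack, "CorrelationStack"))
  ns <- nSubjects(stack)
  if (ns < 3L) stop("need at least 3 subjects for jackknife", call. = FALSE)
  loo <- lapply(seq_len(ns), function(k) {
    sub <- new("CorrelationStack", matrices = stack@matrices[-k],
               roiLabels = stack@roiLabels)
    groupR(fisherAverage(sub))
  })
  sim <- diag(1, ns)
  for (i in seq_len(ns - 1L)) for (j in seq(i + 1L, ns)) {
    sim[i, j] <- sim[j, i] <- cosineSimilarity(loo[[i]], loo[[j]])
  }
  off <- sim[upper.tri(sim)]
  attr(sim, "minOffDiag") <- min(off)
  attr(sim, "maxOffDiag") <- max(off)
  sim
}
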