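#' Extract the weight matrix to analyse from a group matrix
#'
#' Downstream stages operate on `w = r^2` by default: squaring neglects
#' the sign of a correlation while preserving the ranking of magnitudes.
#' `"r"` and `"abs_r"` are provided for sensitivity analyses; thresholds
#' found on the `r2` scale correspond to `sqrt(threshold)` on the
#' correlation scale.
#'
#' @param group a [GroupMatrix-class] or a plain symmetric matrix (used
#'   as-is when `mode = "r2"` squares its off-diagonal... for a plain
#'   matrix the mode transform is applied directly).
#' @param mode one of `"r2"`, `"r"`, `"abs_r"`.
#' @return an N x N symmetric weight matrix with zero diagonal.
#' @export
groupWeights <- function(group, mode = c("r2", "r", "abs_r")) {
  mode <- match.arg(mode)
  r <- if (is(group, "GroupMatrix")) groupR(group) else as.matrix(group)
  w <- switch(mode, r2 = r^2, r = r, abs_r = abs(r))
  diag(w) <- 0
  w
}

#' Rank the edges of a weight matrix in increasing order
#'
#' Every unordered pair (i, j), i < j, is listed once; the order is a
#' stable total order: increasing weight, ties broken lexicographically by
#' (i, j). This is the removal order of the percolation process.
#'
#' @param w symmetric N x N weight matrix (diagonal ignored).
#' @return data.frame with columns `i`, `j`, `weight`, ordered.
#' @export
rankEdges <- function(w) {
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  edges <- data.frame(i = ut[, 1L], j = ut[, 2L], weight = w[ut])
  edges <- edges[order(edges$weight, edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Component-tracking percolation of a weighted network
#'
#' Removes every link of the complete weighted graph one at a time, in
#' increasing weight order (ties broken lexicographically), and records
#' the number of connected components after each removal. Isolated nodes
#' count as components; the curve ends at N when all links are gone.
#' Implemented as the time-reversal of a union-find aggregation (adding
#' links in decreasing order), which yields the exact component count
#' after every single removal in O(M alpha) time.
#'
#' @param w symmetric N x N weight matrix, or a [GroupMatrix-class] (whose
#'   `r^2` weights are used).
#' @param mode weight mode when `w` is a [GroupMatrix-class]; see
#'   [groupWeights()].
#' @return a [PercolationCurve-class].
#' @export
percolate <- function(w, mode = "r2") {
  if (is(w, "GroupMatrix")) w <- groupWeights(w, mode)
  n <- nrow(w)
  edges <- rankEdges(w)
  m <- nrow(edges)
  if (m == 0L) {
    return(new("PercolationCurve", weights = numeric(),
               nComponents = integer(), newborn = logical(),
               nNodes = as.integer(n), initialComponents = as.integer(n)))
  }
  # comps[k] = number of components of the graph holding edges k..m
  # (i.e. after removing the k-1 smallest edges); computed by union-find
  # over edges added from largest to smallest.
  parent <- seq_len(n)
  comps <- integer(m + 1L)
  comps[m + 1L] <- n
  cnt <- n
  for (k in m:1) {
    ri <- edges$i[k]
    while (parent[ri] != ri) { parent[ri] <- parent[parent[ri]]; ri <- parent[ri] }
    rj <- edges$j[k]
    while (parent[rj] != rj) { parent[rj] <- parent[parent[rj]]; rj <- parent[rj] }
    if (ri != rj) {
      parent[ri] <- rj
      cnt <- cnt - 1L
    }
    comps[k] <- cnt
  }
  nAfter <- comps[-1L]                     # count after removing edge k
  initial <- comps[1L]                     # full graph
  newborn <- diff(c(initial, nAfter)) > 0L
  new("PercolationCurve", weights = edges$weight,
      nComponents = as.integer(nAfter), newborn = newborn,
      nNodes = as.integer(n), initialComponents = as.integer(initial))
}

#' Plateau lengths of a percolation curve
#'
#' A plateau is a run of removals with no change in component count; its
#' length is the weight increment between two consecutive newborn-component
#' events. The first newborn event is paired with the minimum edge weight
#' of the graph, so the lengths sum telescopically to (weight of last
#' newborn event) - (minimum edge weight).
#'
#' @param curve a [PercolationCurve-class].
#' @return a [PlateauSet-class] with one plateau per transition from n to
#'   n+1 components (i.e. `nNodes - initialComponents` plateaux).
#' @export
plateauLengths <- function(curve) {
  stopifnot(is(curve, "PercolationCurve"))
  nb <- curve@weights[curve@newborn]
  if (!length(nb)) {
    return(new("PlateauSet", lengths = numeric(), startWeights = numeric(),
               endWeights = numeric()))
  }
  start <- c(min(curve@weights), nb[-length(nb)])
  new("PlateauSet", lengths = nb - start, startWeights = start,
      endWeights = nb)
}

#' Select significant percolation thresholds against a null ensemble
#'
#' Flags the real plateaux whose length exceeds the null mean plus
#' `kSd` standard deviations and returns their start-of-plateau weights,
#' sorted in decreasing order. These weights are the thresholds at which
#' the real network holds a stable configuration that the
#' spectrum-matched randomizations do not reproduce.
#'
#' Two comparison rules are available. `"matched"` (default) compares the
#' m-th real plateau (the transition from m to m+1 components, for a
#' connected graph) against the mean + `kSd` SD band of the m-th plateau
#' lengths across null curves — the pointwise confidence band along the
#' percolation curve. `"pooled"` lumps every null plateau length into one
#' distribution and uses its global mean + `kSd` SD as a single cutoff.
#' Plateau lengths are strongly heavy-tailed along the curve (the last
#' few transitions happen in the sparse upper tail of the weight
#' distribution, where gaps are orders of magnitude larger than in the
#' bulk), so under the pooled rule every null curve's own terminal
#' plateau almost always exceeds the pooled cutoff and the rule loses
#' specificity; the matched rule compares tail against tail and bulk
#' against bulk. When a real transition index is missing from the null
#' curves (different initial component counts), the pooled cutoff is used
#' for it as a fallback.
#'
#' @param real a [PlateauSet-class] from the observed network.
#' @param nullPlateaus list of [PlateauSet-class], one per null curve
#'   (at least 2).
#' @param kSd number of null standard deviations above the null mean;
#'   default 4.
#' @param comparison `"matched"` (per-transition bands) or `"pooled"`.
#' @return numeric vector of selected threshold weights (possibly empty),
#'   decreasing, with attributes `nullMean` and `nullSd` (pooled
#'   statistics), `cutoff` (the cutoff applied to each real plateau, in
#'   plateau order), `comparison` and `perCurveMeans` (mean plateau
#'   length of each null curve).
#' @export
selectThresholds <- function(real, nullPlateaus, kSd = 4,
                             comparison = c("matched", "pooled")) {
  comparison <- match.arg(comparison)
  stopifnot(is(real, "PlateauSet"), length(nullPlateaus) >= 2L)
  nullLens <- lapply(nullPlateaus, function(p) {
    stopifnot(is(p, "PlateauSet"))
    p@lengths
  })
  pool <- unlist(nullLens)
  if (!length(pool)) stop("null ensemble contributed no plateaux",
                          call. = FALSE)
  mu <- mean(pool)
  sigma <- if (length(pool) > 1L) sd(pool) else 0
  pooledCutoff <- mu + kSd * sigma
  nReal <- length(real@lengths)
  cutoff <- rep(pooledCutoff, nReal)
  if (comparison == "matched" && nReal) {
    for (m in seq_len(nReal)) {
      vals <- unlist(lapply(nullLens, function(v)
        if (length(v) >= m) v[m] else NULL))
      if (length(vals) >= 2L)
        cutoff[m] <- mean(vals) + kSd * sd(vals)
    }
  }
  sig <- real@lengths > cutoff
  sel <- real@startWeights[sig]
  ord <- order(sel, decreasing = TRUE)
  sel <- sel[ord]
  attr(sel, "nullMean") <- mu
  attr(sel, "nullSd") <- sigma
  attr(sel, "cutoff") <- cutoff
  attr(sel, "comparison") <- comparison
  attr(sel, "perCurveMeans") <- vapply(nullLens, mean, numeric(1))
  sel
}

#' Thresholded snapshot of the weighted network
#'
#' Keeps every edge with weight >= `threshold` (strictly smaller weights
#' are discarded); the node set is always all N nodes, so the snapshot's
#' component partition matches the percolation state just before the first
#' removal of a weight >= `threshold`.
#'
#' @param w symmetric weight matrix or [GroupMatrix-class].
#' @param threshold nonnegative weight cutoff.
#' @param labels optional node labels (taken from the [GroupMatrix-class]
#'   when given one).
#' @param mode weight mode for a [GroupMatrix-class] input.
#' @return an [igraph::graph] with vertex attributes `name`, `component`,
#'   `degree` and edge attribute `weight`.
#' @export
snapshotGraph <- function(w, threshold, labels = NULL, mode = "r2") {
  stopifnot(threshold >= 0)
  if (is(w, "GroupMatrix")) {
    if (is.null(labels)) labels <- roiLabels(w)
    w <- groupWeights(w, mode)
  }
  n <- nrow(w)
  if (is.null(labels)) labels <- paste0("ROI", seq_len(n))
  keep <- w
  keep[w < threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(keep, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- labels
  igraph::V(g)$component <- igraph::components(g)$membership
  igraph::V(g)$degree <- igraph::degree(g)
  g
}
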