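# Decreasing-weight edge order; ties broken lexicographically by (i, j)
# like rankEdges().
.rankEdgesDecreasing <- function(w) {
  edges <- rankEdges(w)
  edges <- edges[order(-edges$weight, edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

.asWeightMatrix <- function(w, mode = "r2") {
  if (is(w, "GroupMatrix")) groupWeights(w, mode) else {
    w <- as.matrix(w)
    diag(w) <- 0
    w
  }
}

.weightLabels <- function(w, labels) {
  if (!is.null(labels)) return(labels)
  if (is(w, "GroupMatrix")) return(roiLabels(w))
  if (!is.null(colnames(w))) return(colnames(w))
  paste0("ROI", seq_len(nrow(if (is(w, "GroupMatrix")) groupR(w) else w)))
}

#' Directed Maximum Spanning Forest by row maxima
#'
#' Keeps, for every node i, only its single strongest link: a directed arc
#' i -> argmax_j w_ij (self excluded; row ties broken by the smallest
#' partner index). The relation is not symmetric — w_ij being the
#' strongest link of i does not make w_ji the strongest link of j — so the
#' result is a directed network of exactly N arcs whose undirected support
#' is a loop-free forest. Reciprocated pairs (mutual strongest partners)
#' are reported; in resting-state data they are typically bilaterally
#' mirrored regions.
#'
#' @param w symmetric N x N weight matrix or [GroupMatrix-class]
#'   (`r^2` weights).
#' @param labels optional node labels.
#' @param mode weight mode for a [GroupMatrix-class] input.
#' @return a [SpanningForest-class].
#' @export
msfRowMax <- function(w, labels = NULL, mode = "r2") {
  labels <- .weightLabels(w, labels)
  w <- .asWeightMatrix(w, mode)
  n <- nrow(w)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  target <- integer(n)
  aw <- numeric(n)
  for (i in seq_len(n)) {
    row <- w[i, ]
    row[i] <- -Inf
    if (n > 2L && length(unique(row[-i])) == 1L)
      warning("node ", i, ": all candidate weights equal; ",
              "arc assigned by smallest-index tie rule", call. = FALSE)
    target[i] <- which.max(row)      # which.max takes the first maximum
    aw[i] <- row[target[i]]
  }
  arcs <- cbind(source = seq_len(n), target = target)
  mutual <- which(target[target] == seq_len(n) & seq_len(n) < target)
  rec <- cbind(i = mutual, j = target[mutual])
  und <- igraph::graph_from_edgelist(
    cbind(pmin(arcs[, 1L], arcs[, 2L]), pmax(arcs[, 1L], arcs[, 2L])),
    directed = FALSE)
  und <- igraph::add_vertices(und, max(0L, n - igraph::vcount(und)))
  membership <- as.integer(igraph::components(und)$membership)
  new("SpanningForest", arcs = arcs, arcWeights = aw,
      membership = membership, reciprocated = rec, roiLabels = labels)
}

#' Maximum Spanning Forest by greedy list descent
#'
#' Equivalent construction from scratch: rank all pairwise weights in
#' decreasing order, walk the list from the top and add a link if at least
#' one of its two nodes still has degree zero, otherwise discard it; stop
#' when every node has degree at least one. With pairwise-distinct weights
#' the undirected edge set equals the undirected support of
#' [msfRowMax()].
#'
#' @inheritParams msfRowMax
#' @return data.frame of undirected edges with columns `i`, `j`, `weight`
#'   (i < j), in the order they were added.
#' @export
msfGreedy <- function(w, mode = "r2") {
  w <- .asWeightMatrix(w, mode)
  n <- nrow(w)
  edges <- .rankEdgesDecreasing(w)
  deg <- integer(n)
  keep <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]
    if (deg[i] == 0L || deg[j] == 0L) {
      keep[k] <- TRUE
      deg[i] <- deg[i] + 1L
      deg[j] <- deg[j] + 1L
      if (all(deg >= 1L)) break
    }
  }
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Complete a Maximum Spanning Forest into a Maximum Spanning Tree
#'
#' Walks the weights not used by the forest in decreasing order and adds a
#' link whenever its two endpoints belong to different components, merging
#' them (union-find), until a single component spans all N nodes. The
#' result is connected, loop-free, has N-1 edges and attains the maximum
#' total weight over all spanning trees (Kruskal's argument: the forest
#' edges are each the heaviest edge incident to some node and belong to a
#' maximum spanning tree when weights are distinct).
#'
#' @param forest a [SpanningForest-class] built from the same weights.
#' @param w the weight matrix (or [GroupMatrix-class]) the forest came
#'   from.
#' @param mode weight mode for a [GroupMatrix-class] input.
#' @return a [SpanningTree-class].
#' @export
mstComplete <- function(forest, w, mode = "r2") {
  stopifnot(is(forest, "SpanningForest"))
  w <- .asWeightMatrix(w, mode)
  n <- nrow(w)
  if (n != length(forest@roiLabels))
    stop("forest and weight matrix disagree on N", call. = FALSE)
  und <- unique(cbind(pmin(forest@arcs[, 1L], forest@arcs[, 2L]),
                      pmax(forest@arcs[, 1L], forest@arcs[, 2L])))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  ei <- und[, 1L]; ej <- und[, 2L]; ew <- w[und]
  for (k in seq_along(ei)) parent[find(ei[k])] <- find(ej[k])

  inForest <- matrix(FALSE, n, n)
  inForest[und] <- TRUE
  edges <- .rankEdgesDecreasing(w)
  nComp <- length(unique(vapply(seq_len(n), find, integer(1))))
  for (k in seq_len(nrow(edges))) {
    if (nComp == 1L) break
    i <- edges$i[k]; j <- edges$j[k]
    if (inForest[i, j]) next
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      ei <- c(ei, i); ej <- c(ej, j); ew <- c(ew, edges$weight[k])
      nComp <- nComp - 1L
    }
  }
  if (nComp != 1L)
    stop("weight matrix has disconnected support: no spanning tree exists",
         call. = FALSE)
  ord <- order(-ew, ei, ej)
  new("SpanningTree",
      edges = cbind(ei, ej)[ord, , drop = FALSE],
      edgeWeights = ew[ord], totalWeight = sum(ew),
      roiLabels = forest@roiLabels)
}

#' Degree profile of a spanning structure
#'
#' For a [SpanningForest-class] the in-degree distribution is profiled
#' (every node has out-degree 1, so in-degree 0 is common in star-like
#' forests); for a [SpanningTree-class] the plain degree. The chain score
#' is the fraction of nodes with undirected degree at most 2: a pure path
#' scores 1, a star on m >= 4 nodes scores (m-1)/m.
#'
#' @param structure a [SpanningForest-class] or [SpanningTree-class].
#' @return a [DegreeProfile-class].
#' @export
degreeProfiles <- function(structure) {
  n <- length(structure@roiLabels)
  if (is(structure, "SpanningForest")) {
    deg <- tabulate(structure@arcs[, 2L], nbins = n)
    und <- unique(cbind(pmin(structure@arcs[, 1L], structure@arcs[, 2L]),
                        pmax(structure@arcs[, 1L], structure@arcs[, 2L])))
  } else if (is(structure, "SpanningTree")) {
    deg <- tabulate(c(structure@edges), nbins = n)
    und <- structure@edges
  } else stop("structure must be a SpanningForest or SpanningTree",
              call. = FALSE)
  undDeg <- tabulate(c(und), nbins = n)
  vals <- sort(unique(deg))
  hist <- vapply(vals, function(v) sum(deg == v), integer(1))
  names(hist) <- vals
  new("DegreeProfile", degrees = as.integer(deg), histogram = hist,
      fractions = hist / n, maxDegree = max(deg),
      chainScore = mean(undDeg <= 2L))
}

#' Per-component summary of a spanning forest
#'
#' @param forest a [SpanningForest-class].
#' @param groups optional named character vector mapping ROI labels to
#'   anatomical group labels; absent labels yield empty group columns.
#' @return data.frame with one row per component: `component`, `size`,
#'   `members`, `groups`, `reciprocated` (is the component a mutual
#'   strongest-partner pair), `chain_score`.
#' @export
componentSummary <- function(forest, groups = NULL) {
  stopifnot(is(forest, "SpanningForest"))
  n <- length(forest@roiLabels)
  und <- unique(cbind(pmin(forest@arcs[, 1L], forest@arcs[, 2L]),
                      pmax(forest@arcs[, 1L], forest@arcs[, 2L])))
  undDeg <- tabulate(c(und), nbins = n)
  recSet <- if (nrow(forest@reciprocated))
    paste(forest@reciprocated[, 1L], forest@reciprocated[, 2L]) else character()
  comp <- sort(unique(forest@membership))
  rows <- lapply(comp, function(cid) {
    mem <- which(forest@membership == cid)
    grp <- if (is.null(groups)) "" else
      paste(unique(groups[forest@roiLabels[mem]]), collapse = ";")
    isPair <- length(mem) == 2L &&
      paste(min(mem), max(mem)) %in% recSet
    data.frame(component = cid, size = length(mem),
               members = paste(forest@roiLabels[mem], collapse = ";"),
               groups = grp,
               reciprocated = isPair,
               chain_score = mean(undDeg[mem] <= 2L))
  })
  do.call(rbind, rows)
}

#' Convert spanning structures to igraph graphs
#'
#' @param x a [SpanningForest-class] (directed graph) or
#'   [SpanningTree-class] (undirected graph).
#' @return an [igraph::graph] with `name` vertex attribute and `weight`
#'   edge attribute.
#' @export
asGraph <- function(x) {
  if (is(x, "SpanningForest")) {
    g <- igraph::graph_from_edgelist(x@arcs, directed = TRUE)
    g <- igraph::add_vertices(g, max(0L, length(x@roiLabels) -
                                       igraph::vcount(g)))
    igraph::E(g)$weight <- x@arcWeights
  } else if (is(x, "SpanningTree")) {
    g <- igraph::graph_from_edgelist(x@edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(x@roiLabels) -
                                       igraph::vcount(g)))
    igraph::E(g)$weight <- x@edgeWeights
  } else stop("x must be a SpanningForest or SpanningTree", call. = FALSE)
  igraph::V(g)$name <- x@roiLabels
  g
}
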