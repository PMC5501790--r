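# Shared fixtures and independent oracles.

# Random symmetric weight matrix with zero diagonal; entries iid U(0, 1),
# pairwise distinct with probability 1.
randomWeightMatrix <- function(n) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2)
  w + t(w)
}

# Random correlation matrix: sample correlation of a Gaussian data matrix
# (full rank for t > n).
randomCorrelationMatrix <- function(n, t = 4 * n) {
  cor(matrix(rnorm(t * n), t, n))
}

# The 4-node worked example used throughout the spanning tests:
# arcs 1<->2 and 3<->4; MST completion adds edge 2-3 (weight .4).
fourNodeExample <- function() {
  matrix(c(0, .9, .2, .3,
           .9, 0, .4, .1,
           .2, .4, 0, .8,
           .3, .1, .8, 0), 4, 4, byrow = TRUE)
}

# Independent maximum-spanning-tree total weight via igraph's Kruskal on
# negated weights.
igraphMaxSpanningWeight <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(-w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  -sum(igraph::E(igraph::mst(g))$weight)
}

# Exhaustive maximum-spanning-tree total weight by enumerating every
# labelled tree on n nodes through its Pruefer sequence (n^(n-2) trees of
# the complete graph). Only sensible for n <= 7.
bruteMaxSpanningWeight <- function(w) {
  n <- nrow(w)
  if (n == 2L) return(w[1L, 2L])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- -Inf
  for (r in seq_len(nrow(seqs))) {
    prf <- seqs[r, ]
    deg <- rep(1L, n)
    for (v in prf) deg[v] <- deg[v] + 1L
    total <- 0
    avail <- deg
    for (v in prf) {
      leaf <- which(avail == 1L)[1L]
      total <- total + w[leaf, v]
      avail[leaf] <- 0L
      avail[v] <- avail[v] - 1L
    }
    rest <- which(avail == 1L)
    total <- total + w[rest[1L], rest[2L]]
    if (total > best) best <- total
  }
  best
}

# Component count after removing the first k edges of the ranked list,
# recomputed from scratch with igraph's flood fill.
bruteComponentCounts <- function(w) {
  n <- nrow(w)
  edges <- rankEdges(w)
  vapply(seq_len(nrow(edges)), function(k) {
    rest <- edges[-seq_len(k), , drop = FALSE]
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(rest))
      g <- igraph::add_edges(g, t(as.matrix(rest[, c("i", "j")])))
    as.integer(igraph::components(g)$no)
  }, integer(1))
}

# Tiny three-module cohort spec used by several integration tests.
tinyCohortSpec <- function(seed = 11L, nSubjects = 5L, nTimepoints = 120L,
                           noise = 0.1) {
  cohortSpec(nSubjects = nSubjects, nTimepoints = nTimepoints,
             modules = list(a = 1:4, b = 5:8, c = 9:10),
             topology = c("chain", "star", "pair"),
             rWithin = 0.6, rBetween = 0.1, subjectNoiseSd = noise,
             seed = seed)
}
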