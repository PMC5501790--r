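#' @import methods
#' @importFrom stats cor sd pt p.adjust rnorm setNames
#' @importFrom utils head tail
NULL

.checkSquareSym <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m)) return("not a numeric matrix")
  if (nrow(m) != ncol(m)) return("not square")
  if (anyNA(m)) return("contains missing values")
  if (max(abs(m - t(m))) > tol) return("not symmetric")
  NULL
}

#' Cohort specification for the synthetic time-series generator
#'
#' Describes a cohort of subjects whose region-of-interest (ROI) time series
#' are drawn from a planted population correlation matrix with modular
#' structure. Modules are disjoint groups of ROI indices, each with a
#' topology (`"chain"`, `"star"`, `"clique"` or `"pair"`) that determines
#' which within-module pairs receive the full within-module correlation
#' `rWithin`; non-adjacent within-module pairs decay geometrically toward
#' the between-module level `rBetween`. Subject-level heterogeneity is
#' injected on the Fisher-z scale with standard deviation `subjectNoiseSd`.
#'
#' @slot nSubjects number of subjects in the cohort.
#' @slot nRois number of ROIs (columns of each time-series matrix).
#' @slot nTimepoints number of time points per subject.
#' @slot modules named list of integer vectors partitioning `1:nRois`.
#' @slot topology character vector, one of chain/star/clique/pair per module.
#' @slot rWithin target correlation for topology-adjacent within-module pairs.
#' @slot rBetween target correlation for between-module pairs.
#' @slot subjectNoiseSd SD of i.i.d. Fisher-z noise added per subject.
#' @slot seed master seed; subject s uses seed `seed*1000 + s`.
#'
#' @seealso [cohortSpec()], [plantedCorrelation()], [generateCohort()]
#' @export
setClass("CohortSpec", representation(
  nSubjects = "integer", nRois = "integer", nTimepoints = "integer",
  modules = "list", topology = "character",
  rWithin = "numeric", rBetween = "numeric",
  subjectNoiseSd = "numeric", seed = "integer"
))

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (object@nSubjects < 1L) msgs <- c(msgs, "nSubjects must be >= 1")
  if (object@nRois < 2L) msgs <- c(msgs, "nRois must be >= 2")
  if (object@nTimepoints < 3L) msgs <- c(msgs, "nTimepoints must be >= 3")
  idx <- sort(unlist(object@modules, use.names = FALSE))
  if (!identical(as.integer(idx), seq_len(object@nRois)))
    msgs <- c(msgs, "modules must partition 1:nRois exactly")
  if (length(object@topology) != length(object@modules))
    msgs <- c(msgs, "one topology per module required")
  if (!all(object@topology %in% c("chain", "star", "clique", "pair")))
    msgs <- c(msgs, "topology must be chain, star, clique or pair")
  pairSizes <- lengths(object@modules)[object@topology == "pair"]
  if (any(pairSizes != 2L))
    msgs <- c(msgs, "pair modules must have exactly 2 members")
  if (object@rWithin < 0 || object@rWithin >= 1)
    msgs <- c(msgs, "rWithin must be in [0, 1)")
  if (object@rBetween < 0 || object@rBetween > object@rWithin)
    msgs <- c(msgs, "rBetween must be in [0, rWithin]")
  if (object@subjectNoiseSd < 0) msgs <- c(msgs, "subjectNoiseSd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' A single subject's ROI time series
#'
#' A T x N numeric matrix (rows = time points, columns = ROIs) with a
#' subject identifier. Columns must have nonzero variance and no missing
#' values: a constant ROI signal has no defined Pearson correlation.
#'
#' @slot values T x N numeric matrix; column names are ROI labels.
#' @slot subjectId character scalar.
#' @export
setClass("SubjectTimeSeries", representation(
  values = "matrix", subjectId = "character"
))

setValidity("SubjectTimeSeries", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (anyNA(v)) return("values contain missing entries")
  if (nrow(v) < 3L) return("need at least 3 time points")
  vars <- apply(v, 2L, stats::var)
  if (any(vars == 0)) {
    bad <- colnames(v)[vars == 0]
    if (is.null(bad)) bad <- which(vars == 0)
    return(paste0("constant column (zero variance): ",
                  paste(bad, collapse = ", ")))
  }
  TRUE
})

#' Stack of per-subject correlation matrices
#'
#' @slot matrices list of N x N symmetric unit-diagonal matrices, one per
#'   subject, all sharing the same ROI order.
#' @slot roiLabels character vector of N ROI labels.
#' @export
setClass("CorrelationStack", representation(
  matrices = "list", roiLabels = "character"
))

setValidity("CorrelationStack", function(object) {
  if (!length(object@matrices)) return("empty stack")
  n <- length(object@roiLabels)
  for (k in seq_along(object@matrices)) {
    m <- object@matrices[[k]]
    bad <- .checkSquareSym(m)
    if (!is.null(bad)) return(sprintf("matrix %d: %s", k, bad))
    if (nrow(m) != n) return(sprintf("matrix %d: dimension != length(roiLabels)", k))
    if (max(abs(diag(m) - 1)) > 1e-8) return(sprintf("matrix %d: diagonal != 1", k))
    if (max(abs(m)) > 1 + 1e-8) return(sprintf("matrix %d: entries outside [-1, 1]", k))
  }
  TRUE
})

#' Group correlation matrix and its squared-weight companion
#'
#' Holds the Fisher-averaged group correlation matrix `r` and the weight
#' matrix `w` with `w_ij = r_ij^2` used by all downstream network stages
#' (squaring neglects the sign of a correlation while preserving the
#' ranking of its magnitude). The diagonal of `w` is zero by convention.
#'
#' @slot r N x N group correlation matrix, unit diagonal.
#' @slot w N x N weight matrix, `w = r^2` off-diagonal, zero diagonal.
#' @slot roiLabels character vector of N ROI labels.
#' @export
setClass("GroupMatrix", representation(
  r = "matrix", w = "matrix", roiLabels = "character"
))

setValidity("GroupMatrix", function(object) {
  bad <- .checkSquareSym(object@r)
  if (!is.null(bad)) return(paste("r:", bad))
  if (max(abs(diag(object@r) - 1)) > 1e-8) return("r diagonal != 1")
  expw <- object@r^2; diag(expw) <- 0
  if (max(abs(object@w - expw)) > 1e-10) return("w != r^2 with zero diagonal")
  if (nrow(object@r) != length(object@roiLabels)) return("roiLabels length mismatch")
  TRUE
})

#' Entrywise inter-subject variability maps
#'
#' Mean, standard deviation and coefficient of variation of the raw
#' (non-Fisher) correlation values across subjects. The CV is reported only
#' on edges whose across-subject Fisher-z values differ from zero after
#' Benjamini-Hochberg FDR control; elsewhere it is `NA`.
#'
#' @slot mean N x N arithmetic mean of subject correlations.
#' @slot sd N x N sample standard deviation (denominator n-1).
#' @slot cv N x N sd/|mean| on FDR-retained edges, `NA` elsewhere.
#' @slot fdrMask N x N logical, `TRUE` where the edge was retained.
#' @slot fdrQ the FDR level used.
#' @export
setClass("VariabilityMaps", representation(
  mean = "matrix", sd = "matrix", cv = "matrix",
  fdrMask = "matrix", fdrQ = "numeric"
))

#' Component-tracking percolation curve
#'
#' Ordered record of the link-removal process: links are removed one at a
#' time in increasing weight order and the number of connected components
#' (isolated nodes included) is recorded after every removal. Events where
#' the component count increased are the "newborn component" events.
#'
#' @slot weights weight of each removed link, in removal order.
#' @slot nComponents component count after each removal.
#' @slot newborn logical, `TRUE` where the count increased.
#' @slot nNodes number of nodes N.
#' @slot initialComponents component count of the full graph.
#' @export
setClass("PercolationCurve", representation(
  weights = "numeric", nComponents = "integer", newborn = "logical",
  nNodes = "integer", initialComponents = "integer"
))

setValidity("PercolationCurve", function(object) {
  n <- length(object@weights)
  if (length(object@nComponents) != n || length(object@newborn) != n)
    return("weights, nComponents and newborn must have equal length")
  if (n > 0L) {
    if (is.unsorted(object@nComponents)) return("component count must be nondecreasing")
    if (object@nComponents[n] != object@nNodes)
      return("final component count must equal nNodes")
    if (is.unsorted(object@weights)) return("removal weights must be nondecreasing")
  }
  TRUE
})

#' Plateau lengths of a percolation curve
#'
#' One plateau per transition from n to n+1 components. Its length is the
#' weight increment between consecutive newborn-component events; the first
#' plateau is measured from the minimum edge weight of the graph, so the
#' lengths sum telescopically to (last newborn weight - minimum weight).
#'
#' @slot lengths plateau lengths (>= 0).
#' @slot startWeights left endpoint of each plateau (used as thresholds).
#' @slot endWeights weight at which the newborn event occurred.
#' @export
setClass("PlateauSet", representation(
  lengths = "numeric", startWeights = "numeric", endWeights = "numeric"
))

setValidity("PlateauSet", function(object) {
  if (length(object@lengths) != length(object@startWeights) ||
      length(object@lengths) != length(object@endWeights))
    return("lengths, startWeights, endWeights must have equal length")
  if (any(object@lengths < -1e-12)) return("plateau lengths must be >= 0")
  TRUE
})

#' Directed Maximum Spanning Forest (strongest-link filter)
#'
#' Keeps, for every node, only the single strongest link: node i sends a
#' directed arc to argmax_j w_ij. The undirected support is a loop-free
#' forest; reciprocated pairs are nodes that are each other's strongest
#' partner.
#'
#' @slot arcs N x 2 integer matrix (source, target), one arc per node.
#' @slot arcWeights weight of each arc.
#' @slot membership integer component id per node (weak connectivity).
#' @slot reciprocated two-column matrix of reciprocated pairs (i < j).
#' @slot roiLabels character node labels.
#' @export
setClass("SpanningForest", representation(
  arcs = "matrix", arcWeights = "numeric", membership = "integer",
  reciprocated = "matrix", roiLabels = "character"
))

setValidity("SpanningForest", function(object) {
  n <- length(object@roiLabels)
  if (nrow(object@arcs) != n) return("must have exactly one arc per node")
  if (!identical(as.integer(object@arcs[, 1L]), seq_len(n)))
    return("every node must have out-degree exactly 1")
  if (any(object@arcs[, 1L] == object@arcs[, 2L])) return("self-arcs not allowed")
  TRUE
})

#' Maximum Spanning Tree
#'
#' @slot edges (N-1) x 2 integer matrix of undirected edges.
#' @slot edgeWeights weight per edge.
#' @slot totalWeight sum of edge weights (maximal over spanning trees).
#' @slot roiLabels character node labels.
#' @export
setClass("SpanningTree", representation(
  edges = "matrix", edgeWeights = "numeric", totalWeight = "numeric",
  roiLabels = "character"
))

setValidity("SpanningTree", function(object) {
  n <- length(object@roiLabels)
  if (nrow(object@edges) != n - 1L) return("a spanning tree has N-1 edges")
  g <- igraph::graph_from_edgelist(object@edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  if (igraph::components(g)$no != 1L) return("tree must be connected")
  if (abs(object@totalWeight - sum(object@edgeWeights)) > 1e-8)
    return("totalWeight != sum(edgeWeights)")
  TRUE
})

#' Degree profile of a spanning structure
#'
#' Histogram of node (in-)degrees, the fraction of nodes at each degree,
#' the maximum degree and a chain score: the fraction of nodes whose
#' undirected degree is at most 2 (a pure path scores 1, a star hub drags
#' the score down). Chain-like scaffolds have low maximum in-degree and a
#' chain score near 1; star-like (randomized) scaffolds show hubs.
#'
#' @slot degrees integer degree per node.
#' @slot histogram named integer vector: count of nodes per degree value.
#' @slot fractions named numeric vector summing to 1.
#' @slot maxDegree largest degree observed.
#' @slot chainScore fraction of nodes with undirected degree <= 2.
#' @export
setClass("DegreeProfile", representation(
  degrees = "integer", histogram = "integer", fractions = "numeric",
  maxDegree = "integer", chainScore = "numeric"
))

#' Spectrum-preserving null ensemble
#'
#' Random correlation matrices sharing the eigenvalue spectrum of a source
#' group matrix: each member is Q diag(lambda) Q' for a Haar-random
#' orthogonal Q, brought back to unit diagonal by a sequence of Givens
#' rotations (which preserve the spectrum and positive semidefiniteness).
#'
#' @slot matrices list of N x N correlation matrices.
#' @slot seeds integer seed used for each member.
#' @slot sourceSpectrum the preserved eigenvalues (decreasing, sum N).
#' @export
setClass("NullEnsemble", representation(
  matrices = "list", seeds = "integer", sourceSpectrum = "numeric"
))

setValidity("NullEnsemble", function(object) {
  if (length(object@matrices) != length(object@seeds))
    return("one seed per member required")
  lam <- sort(object@sourceSpectrum, decreasing = TRUE)
  if (any(lam < -1e-10)) return("spectrum must be nonnegative")
  if (length(lam) && abs(sum(lam) - length(lam)) > 1e-8)
    return("spectrum must sum to N (trace of a correlation matrix)")
  TRUE
})
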