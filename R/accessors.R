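#' @rdname CorrelationStack-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname CorrelationStack-class
#' @export
setGeneric("nRois", function(x) standardGeneric("nRois"))

#' @rdname CorrelationStack-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname CorrelationStack-class
#' @export
setGeneric("subjectMatrices", function(x) standardGeneric("subjectMatrices"))

#' @rdname GroupMatrix-class
#' @export
setGeneric("groupR", function(x) standardGeneric("groupR"))

#' @rdname GroupMatrix-class
#' @export
setGeneric("groupW", function(x) standardGeneric("groupW"))

setMethod("roiLabels", "CorrelationStack", function(x) x@roiLabels)
setMethod("roiLabels", "GroupMatrix", function(x) x@roiLabels)
setMethod("roiLabels", "SpanningForest", function(x) x@roiLabels)
setMethod("roiLabels", "SpanningTree", function(x) x@roiLabels)
setMethod("nRois", "CorrelationStack", function(x) length(x@roiLabels))
setMethod("nRois", "GroupMatrix", function(x) length(x@roiLabels))
setMethod("nSubjects", "CorrelationStack", function(x) length(x@matrices))
setMethod("subjectMatrices", "CorrelationStack", function(x) x@matrices)
setMethod("groupR", "GroupMatrix", function(x) x@r)
setMethod("groupW", "GroupMatrix", function(x) x@w)

#' @rdname SubjectTimeSeries-class
#' @param x a `SubjectTimeSeries`.
#' @export
timeSeriesValues <- function(x) {
  stopifnot(is(x, "SubjectTimeSeries"))
  x@values
}

#' @rdname SubjectTimeSeries-class
#' @export
subjectId <- function(x) {
  stopifnot(is(x, "SubjectTimeSeries"))
  x@subjectId
}

#' @rdname PercolationCurve-class
#' @param curve a `PercolationCurve`.
#' @return `percolationEvents()`: a data.frame with columns
#'   `weight_removed`, `n_components`, `newborn`.
#' @export
percolationEvents <- function(curve) {
  stopifnot(is(curve, "PercolationCurve"))
  data.frame(weight_removed = curve@weights,
             n_components = curve@nComponents,
             newborn = curve@newborn)
}

#' @rdname PlateauSet-class
#' @param x a `PlateauSet`.
#' @export
plateauTable <- function(x) {
  stopifnot(is(x, "PlateauSet"))
  data.frame(start_weight = x@startWeights,
             end_weight = x@endWeights,
             length = x@lengths)
}

#' @rdname SpanningForest-class
#' @param forest a `SpanningForest`.
#' @return `forestArcs()`: a data.frame with columns `source`, `target`,
#'   `weight`, `reciprocated` (labels where available).
#' @export
forestArcs <- function(forest) {
  stopifnot(is(forest, "SpanningForest"))
  rec <- paste(pmin(forest@arcs[, 1L], forest@arcs[, 2L]),
               pmax(forest@arcs[, 1L], forest@arcs[, 2L]))
  recSet <- if (nrow(forest@reciprocated))
    paste(forest@reciprocated[, 1L], forest@reciprocated[, 2L]) else character()
  data.frame(source = forest@roiLabels[forest@arcs[, 1L]],
             target = forest@roiLabels[forest@arcs[, 2L]],
             weight = forest@arcWeights,
             reciprocated = rec %in% recSet)
}

#' @rdname SpanningTree-class
#' @param tree a `SpanningTree`.
#' @export
treeEdges <- function(tree) {
  stopifnot(is(tree, "SpanningTree"))
  data.frame(node1 = tree@roiLabels[tree@edges[, 1L]],
             node2 = tree@roiLabels[tree@edges[, 2L]],
             weight = tree@edgeWeights)
}

#' @rdname SpanningTree-class
#' @export
totalWeight <- function(tree) {
  stopifnot(is(tree, "SpanningTree"))
  tree@totalWeight
}

#' @rdname NullEnsemble-class
#' @param x a `NullEnsemble`.
#' @export
ensembleMatrices <- function(x) {
  stopifnot(is(x, "NullEnsemble"))
  x@matrices
}

#' @rdname NullEnsemble-class
#' @export
sourceSpectrum <- function(x) {
  stopifnot(is(x, "NullEnsemble"))
  x@sourceSpectrum
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d subjects, %d ROIs, %d time points\n",
              object@nSubjects, object@nRois, object@nTimepoints))
  cat(sprintf("  modules: %s\n",
              paste(sprintf("%s[%d:%s]", names(object@modules),
                            lengths(object@modules), object@topology),
                    collapse = " ")))
  cat(sprintf("  rWithin=%.3g rBetween=%.3g subjectNoiseSd=%.3g seed=%d\n",
              object@rWithin, object@rBetween, object@subjectNoiseSd,
              object@seed))
})

setMethod("show", "SubjectTimeSeries", function(object) {
  cat(sprintf("SubjectTimeSeries '%s': %d time points x %d ROIs\n",
              object@subjectId, nrow(object@values), ncol(object@values)))
})

setMethod("show", "CorrelationStack", function(object) {
  cat(sprintf("CorrelationStack: %d subjects, %d ROIs\n",
              nSubjects(object), nRois(object)))
})

setMethod("show", "GroupMatrix", function(object) {
  offd <- object@r[upper.tri(object@r)]
  cat(sprintf("GroupMatrix: %d ROIs; off-diagonal r in [%.3f, %.3f]\n",
              nRois(object), min(offd), max(offd)))
})

setMethod("show", "PercolationCurve", function(object) {
  cat(sprintf(
    "PercolationCurve: %d nodes, %d removals, components %d -> %d (%d newborn events)\n",
    object@nNodes, length(object@weights), object@initialComponents,
    if (length(object@nComponents)) max(object@nComponents) else
      object@initialComponents,
    sum(object@newborn)))
})

setMethod("show", "PlateauSet", function(object) {
  cat(sprintf("PlateauSet: %d plateaux, max length %.4g\n",
              length(object@lengths),
              if (length(object@lengths)) max(object@lengths) else NA_real_))
})

setMethod("show", "SpanningForest", function(object) {
  cat(sprintf(
    "SpanningForest: %d arcs, %d components, %d reciprocated pairs\n",
    nrow(object@arcs), length(unique(object@membership)),
    nrow(object@reciprocated)))
})

setMethod("show", "SpanningTree", function(object) {
  cat(sprintf("SpanningTree: %d nodes, %d edges, total weight %.4f\n",
              length(object@roiLabels), nrow(object@edges),
              object@totalWeight))
})

setMethod("show", "DegreeProfile", function(object) {
  cat(sprintf("DegreeProfile: max degree %d, chain score %.3f\n",
              object@maxDegree, object@chainScore))
  print(object@histogram)
})

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf("NullEnsemble: %d spectrum-preserving members (N = %d)\n",
              length(object@matrices), length(object@sourceSpectrum)))
})
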