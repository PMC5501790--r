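#' Construct a cohort specification
#'
#' @param nSubjects,nRois,nTimepoints cohort dimensions. `nRois` may be
#'   omitted, in which case it is taken from the module partition.
#' @param modules named list of integer vectors partitioning `1:nRois`.
#' @param topology character vector (recycled) choosing, per module, which
#'   pairs are "adjacent" and so carry the full `rWithin` correlation:
#'   `"chain"` (consecutive members), `"star"` (first member is the hub),
#'   `"clique"` (all pairs), `"pair"` (a 2-ROI module).
#' @param rWithin target correlation of adjacent within-module pairs, in
#'   \[0, 1).
#' @param rBetween target correlation of between-module pairs, in
#'   \[0, rWithin\].
#' @param subjectNoiseSd SD of subject-level i.i.d. noise added to the
#'   planted matrix on the Fisher-z scale.
#' @param seed master seed; subject `s` derives seed `seed*1000 + s`.
#' @return a validated [CohortSpec-class] object. A warning is emitted when
#'   `nTimepoints <= nRois` (sample correlation matrices are then rank
#'   deficient).
#' @examples
#' spec <- cohortSpec(nSubjects = 4, nTimepoints = 100,
#'                    modules = list(a = 1:3, b = 4:5),
#'                    topology = c("chain", "pair"),
#'                    rWithin = 0.6, rBetween = 0.1)
#' @export
cohortSpec <- function(nSubjects, modules, topology,
                       nTimepoints, nRois = length(unlist(modules)),
                       rWithin = 0.6, rBetween = 0.1,
                       subjectNoiseSd = 0.1, seed = 1L) {
  if (is.null(names(modules)))
    names(modules) <- paste0("M", seq_along(modules))
  topology <- rep_len(topology, length(modules))
  spec <- new("CohortSpec",
              nSubjects = as.integer(nSubjects), nRois = as.integer(nRois),
              nTimepoints = as.integer(nTimepoints),
              modules = lapply(modules, as.integer),
              topology = topology,
              rWithin = as.numeric(rWithin), rBetween = as.numeric(rBetween),
              subjectNoiseSd = as.numeric(subjectNoiseSd),
              seed = as.integer(seed))
  validObject(spec)
  if (spec@nTimepoints <= spec@nRois)
    warning("nTimepoints <= nRois: subject correlation matrices will be ",
            "rank deficient", call. = FALSE)
  spec
}

#' Default chain-module cohort specification
#'
#' The reference synthetic design: 8 chain modules of sizes 15, 11, 8, 7,
#' 6, 5, 4 and 2 (58 ROIs), 40 subjects, 240 time points, adjacent-pair
#' correlation 0.6, between-module correlation 0.1 and subject noise 0.1
#' on the Fisher-z scale. The module sizes span the range from bilateral
#' pairs to a long chain, emulating the mixture of small reciprocated
#' pairs and long chain components that strongest-link filtering of
#' resting-state connectivity exhibits.
#'
#' @param seed master seed.
#' @param ... overrides passed to [cohortSpec()].
#' @return a [CohortSpec-class].
#' @export
defaultChainCohort <- function(seed = 1L, ...) {
  sizes <- c(15L, 11L, 8L, 7L, 6L, 5L, 4L, 2L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  modules <- mapply(seq.int, starts, ends, SIMPLIFY = FALSE)
  names(modules) <- paste0("chain", seq_along(modules))
  topo <- ifelse(sizes == 2L, "pair", "chain")
  args <- list(nSubjects = 40L, nTimepoints = 240L, modules = modules,
               topology = topo, rWithin = 0.6, rBetween = 0.1,
               subjectNoiseSd = 0.1, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohortSpec, args)
}

# Graph distance between module members under the module topology
# (Inf when the topology graph does not connect them, which cannot happen
# for chain/star/clique/pair).
.moduleDistances <- function(members, topology) {
  m <- length(members)
  d <- matrix(0, m, m)
  if (m == 1L) return(d)
  switch(topology,
    chain = {
      d <- abs(outer(seq_len(m), seq_len(m), "-"))
    },
    star = {
      d <- matrix(2, m, m); d[1L, ] <- 1; d[, 1L] <- 1; diag(d) <- 0
    },
    clique = ,
    pair = {
      d <- matrix(1, m, m); diag(d) <- 0
    })
  d
}

#' Topology-adjacency of the planted design
#'
#' Logical N x N matrix marking pairs that are adjacent in their module's
#' topology graph (chain neighbours, hub-leaf pairs, clique pairs). These
#' are the pairs planted at the full `rWithin` level, and the ground truth
#' for strongest-link (MSF) recovery experiments.
#'
#' @param spec a [CohortSpec-class].
#' @return logical N x N symmetric matrix, `FALSE` diagonal.
#' @export
plantedAdjacency <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  n <- spec@nRois
  adj <- matrix(FALSE, n, n)
  for (k in seq_along(spec@modules)) {
    mem <- spec@modules[[k]]
    d <- .moduleDistances(mem, spec@topology[k])
    adj[mem, mem] <- d == 1
  }
  adj
}

# Clip eigenvalues at 0 and renormalize to unit diagonal.
# Returns list(matrix, maxChange).
.psdRepair <- function(a) {
  e <- eigen(a, symmetric = TRUE)
  if (min(e$values) >= 0) {
    return(list(matrix = a, maxChange = 0))
  }
  lam <- pmax(e$values, 0)
  b <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(b))
  b <- b / outer(d, d)
  b <- (b + t(b)) / 2
  diag(b) <- 1
  list(matrix = b, maxChange = max(abs(b - a)))
}

#' Planted population correlation matrix
#'
#' Builds the ground-truth correlation matrix of a cohort specification:
#' topology-adjacent within-module pairs get `rWithin`; a within-module
#' pair at topology distance d gets
#' `rBetween + (rWithin - rBetween) * rWithin^(d-1)` (a geometric decay
#' toward the background, matching an AR(1)-like chain and hub-mediated
#' `r^2` coupling for star leaves); between-module pairs get `rBetween`.
#' Positive semidefiniteness is enforced by clipping negative eigenvalues
#' at zero and renormalizing the diagonal; if that repair moves any entry
#' by more than 0.05 the requested levels are deemed unrealizable and an
#' error names the module with the largest distortion.
#'
#' @param spec a [CohortSpec-class].
#' @return an N x N symmetric, unit-diagonal, positive semidefinite matrix.
#' @export
plantedCorrelation <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  n <- spec@nRois
  a <- matrix(spec@rBetween, n, n)
  for (k in seq_along(spec@modules)) {
    mem <- spec@modules[[k]]
    d <- .moduleDistances(mem, spec@topology[k])
    v <- spec@rBetween + (spec@rWithin - spec@rBetween) *
      ifelse(d >= 1, spec@rWithin^(d - 1), 0)
    v[d == 0] <- 1
    a[mem, mem] <- v
  }
  diag(a) <- 1
  rep <- .psdRepair(a)
  if (rep$maxChange > 0.05) {
    delta <- abs(rep$matrix - a)
    worst <- which.max(vapply(spec@modules, function(mem)
      max(delta[mem, mem]), numeric(1)))
    stop("requested correlation levels are not realizable as a PSD matrix ",
         "(entrywise repair distortion ", format(rep$maxChange, digits = 3),
         " > 0.05) in module '", names(spec@modules)[worst], "'",
         call. = FALSE)
  }
  rep$matrix
}

# Per-subject correlation: planted matrix perturbed on the Fisher-z scale.
.subjectCorrelation <- function(planted, noiseSd, nAttempts = 10L) {
  n <- nrow(planted)
  if (noiseSd == 0) return(planted)
  ut <- upper.tri(planted)
  for (attempt in seq_len(nAttempts)) {
    z <- atanh(pmin(pmax(planted[ut], -1 + 1e-12), 1 - 1e-12))
    z <- z + rnorm(sum(ut), sd = noiseSd)
    a <- matrix(0, n, n)
    a[ut] <- tanh(z)
    a <- a + t(a)
    diag(a) <- 1
    rep <- .psdRepair(a)
    e <- min(eigen(rep$matrix, symmetric = TRUE, only.values = TRUE)$values)
    if (e >= -1e-8) return(rep$matrix)
  }
  stop("could not generate a positive semidefinite subject correlation ",
       "matrix in ", nAttempts, " attempts", call. = FALSE)
}

# T draws from N(0, sigma) via eigendecomposition (PSD-safe; chol would
# reject semidefinite matrices).
.mvnSample <- function(nT, sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(rnorm(nT * nrow(sigma)), nT)
  z %*% (t(e$vectors) * sqrt(lam))
}

#' Generate a synthetic cohort of ROI time series
#'
#' For each subject the planted population correlation matrix is perturbed
#' with i.i.d. Gaussian noise on the Fisher-z scale (so perturbed values
#' stay in (-1, 1)), re-symmetrized, repaired to PSD, and `nTimepoints`
#' samples are drawn from a zero-mean multivariate normal with that
#' correlation. Subject s is seeded with `seed*1000 + s`, making the cohort
#' bitwise reproducible and subject noise independent across subjects.
#'
#' @param spec a [CohortSpec-class].
#' @return a list of [SubjectTimeSeries-class], one per subject, with ROI
#'   labels `ROI1..ROIN`.
#' @examples
#' spec <- cohortSpec(nSubjects = 2, nTimepoints = 50,
#'                    modules = list(a = 1:3, b = 4:5),
#'                    topology = c("chain", "pair"),
#'                    rWithin = 0.6, rBetween = 0.1, seed = 7)
#' cohort <- generateCohort(spec)
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  planted <- plantedCorrelation(spec)
  labels <- paste0("ROI", seq_len(spec@nRois))
  lapply(seq_len(spec@nSubjects), function(s) {
    set.seed((spec@seed * 1000L + s) %% .Machine$integer.max)
    sigma <- .subjectCorrelation(planted, spec@subjectNoiseSd)
    v <- .mvnSample(spec@nTimepoints, sigma)
    colnames(v) <- labels
    new("SubjectTimeSeries", values = v,
        subjectId = sprintf("subj%02d", s))
  })
}
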