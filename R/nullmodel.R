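#' Haar-distributed random orthogonal matrix
#'
#' Draws Q from the rotation-invariant (Haar) measure on the orthogonal
#' group O(N): a standard Gaussian matrix is QR-factorized and the columns
#' of Q are sign-corrected by the signs of diag(R), which removes the
#' sign ambiguity of the factorization and makes the distribution exactly
#' invariant (Mezzadri's recipe). Each entry has mean 0 and variance 1/N.
#'
#' @param n dimension (>= 2).
#' @param seed optional integer seed.
#' @return an n x n orthogonal matrix.
#' @export
haarOrthogonal <- function(n, seed = NULL) {
  stopifnot(n >= 2L)
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(rnorm(n * n), n)
  qrz <- qr(z)
  q <- qr.Q(qrz)
  d <- sign(diag(qr.R(qrz)))
  d[d == 0] <- 1
  q * rep(d, each = n)
}

# Givens rotation in the (i, j) plane bringing a[i, i] to exactly 1 while
# preserving the spectrum. Of the two angles that work, the smaller |angle|
# (smaller |tan|) is taken for numerical stability.
.givensFixDiagonal <- function(a, i, j) {
  aii <- a[i, i]; ajj <- a[j, j]; aij <- a[i, j]
  # (ajj - 1) t^2 + 2 aij t + (aii - 1) = 0 in t = tan(theta)
  qa <- ajj - 1; qb <- 2 * aij; qc <- aii - 1
  disc <- sqrt(qb^2 - 4 * qa * qc)   # > 0: qa > 0 > qc
  t1 <- (-qb + disc) / (2 * qa)
  t2 <- (-qb - disc) / (2 * qa)
  t <- if (abs(t1) <= abs(t2)) t1 else t2
  cth <- 1 / sqrt(1 + t^2)
  sth <- t * cth
  ri <- cth * a[i, ] + sth * a[j, ]
  rj <- -sth * a[i, ] + cth * a[j, ]
  a[i, ] <- ri; a[j, ] <- rj
  ci <- cth * a[, i] + sth * a[, j]
  cj <- -sth * a[, i] + cth * a[, j]
  a[, i] <- ci; a[, j] <- cj
  a[i, i] <- 1
  a
}

#' Random correlation matrix with a fixed eigenvalue spectrum
#'
#' Builds A0 = Q diag(lambda) Q' with Q Haar-orthogonal, then applies a
#' sequence of at most N-1 Givens rotations, each chosen to set one
#' diagonal entry to exactly 1 (possible while the diagonal is not all
#' ones, because the trace is N so some entry is below 1 and some above).
#' Rotations are orthogonal similarities, so the spectrum is untouched and
#' the result is symmetric, positive semidefinite, unit-diagonal — a valid
#' correlation matrix — without any post-hoc PSD adjustment.
#'
#' @param spectrum nonnegative eigenvalues summing to N (tolerance 1e-8).
#' @param seed optional integer seed (drives the Haar draw).
#' @return an N x N correlation matrix whose sorted eigenvalues equal
#'   `spectrum`.
#' @export
fixedSpectrumCorrelation <- function(spectrum, seed = NULL) {
  n <- length(spectrum)
  stopifnot(n >= 2L)
  if (any(spectrum < -1e-10))
    stop("spectrum must be nonnegative", call. = FALSE)
  spectrum <- pmax(spectrum, 0)
  if (abs(sum(spectrum) - n) > 1e-8)
    stop("spectrum must sum to N (trace of a correlation matrix); got ",
         format(sum(spectrum), digits = 10), call. = FALSE)
  q <- haarOrthogonal(n, seed)
  a <- q %*% (spectrum * t(q))
  a <- (a + t(a)) / 2
  eps <- 1e-12
  for (step in seq_len(n)) {
    lo <- which(diag(a) < 1 - eps)[1L]
    hi <- which(diag(a) > 1 + eps)[1L]
    if (is.na(lo) || is.na(hi)) break
    a <- .givensFixDiagonal(a, lo, hi)
    a <- (a + t(a)) / 2
  }
  if (any(abs(diag(a) - 1) > 1e-10))
    stop("Givens sequence failed to restore the unit diagonal ",
         "(this is a bug)", call. = FALSE)
  diag(a) <- 1
  a
}

#' Generate a spectrum-preserving null ensemble
#'
#' Extracts the eigenvalue spectrum of the group correlation matrix
#' (eigenvalues within -1e-8 of zero are clipped to 0 and the spectrum is
#' rescaled to trace N) and draws `n` random correlation matrices with
#' exactly that spectrum via [fixedSpectrumCorrelation()]. Member k is
#' seeded with `masterSeed*10000 + k`. Downstream comparisons against the
#' real network use each member's pointwise square, matching the `r^2`
#' weighting of the observed matrix.
#'
#' @param group a [GroupMatrix-class] (or plain correlation matrix).
#' @param n ensemble size; default 100.
#' @param masterSeed integer master seed.
#' @return a [NullEnsemble-class] (empty when `n = 0`).
#' @export
ensembleGenerate <- function(group, n = 100L, masterSeed = 1L) {
  r <- if (is(group, "GroupMatrix")) groupR(group) else as.matrix(group)
  lam <- eigen((r + t(r)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) < -1e-8)
    stop("group matrix has eigenvalue ", format(min(lam), digits = 4),
         " < -1e-8: not positive semidefinite; repair it upstream ",
         "(eigenvalue clipping) before building nulls", call. = FALSE)
  lam <- pmax(lam, 0)
  lam <- lam * length(lam) / sum(lam)
  seeds <- as.integer((masterSeed * 10000L + seq_len(n)) %%
                        .Machine$integer.max)
  mats <- lapply(seeds, function(s) fixedSpectrumCorrelation(lam, s))
  new("NullEnsemble", matrices = mats, seeds = seeds,
      sourceSpectrum = lam)
}

#' Write / read a null ensemble as delimited text
#'
#' The ensemble is persisted as one tab-separated matrix file per member
#' plus a `manifest.tsv` recording file names, seeds and a hash of the
#' source spectrum, so a stored ensemble is provably matched to its
#' source matrix.
#'
#' @param ensemble a [NullEnsemble-class].
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
writeEnsemble <- function(ensemble, dir) {
  stopifnot(is(ensemble, "NullEnsemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(seq_along(ensemble@matrices), function(k) {
    f <- sprintf("null_%03d.tsv", k)
    utils::write.table(ensemble@matrices[[k]], file.path(dir, f),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    f
  }, character(1))
  manifest <- data.frame(file = files, seed = ensemble@seeds)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(spectrumHash(ensemble@sourceSpectrum),
             file.path(dir, "spectrum_hash.txt"))
  invisible(file.path(dir, "manifest.tsv"))
}

#' Hash of an eigenvalue spectrum
#'
#' A short deterministic digest (sum of scaled eigenvalues folded into
#' hex) used to tag null ensembles with the spectrum they preserve.
#'
#' @param spectrum numeric eigenvalues.
#' @return a character scalar.
#' @export
spectrumHash <- function(spectrum) {
  s <- sort(spectrum, decreasing = TRUE)
  key <- paste(sprintf("%.12g", s), collapse = ",")
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}
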