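---
title: "Percolation and spanning-forest analysis of correlation networks"
author: "NetScaffold authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Percolation and spanning-forest analysis of correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NetScaffold)
```

## The problem

Resting-state functional connectivity studies summarize brain activity as a
weighted network: nodes are grey-matter regions of interest (ROIs), and the
weight of a link is the strength of the Pearson correlation between the two
regions' BOLD time series. Such networks are complete — every pair of
regions has *some* correlation — so the usual first analysis step is to
threshold the matrix, and the usual criticism is that the threshold is
arbitrary. NetScaffold implements a threshold-free alternative built from
three ingredients:

1. **Component-tracking percolation.** Links are removed one at a time in
   increasing weight order and the number of connected components is
   recorded after every removal. Runs of removals during which the count
   does not change ("plateaux") mark stable network configurations; long
   plateaux identify weight ranges over which the network's mesoscale
   organization is robust.
2. **Spectrum-preserving null ensemble.** Plateau lengths are only
   meaningful relative to chance. The null model is an ensemble of random
   *correlation* matrices with exactly the eigenvalue spectrum of the
   observed one — symmetric, unit diagonal, positive semidefinite by
   construction — obtained by a random orthogonal similarity of the
   eigenvalue matrix followed by Givens rotations that restore the unit
   diagonal.
3. **Maximum Spanning Forest and Tree.** Keeping only each node's single
   strongest link yields a directed forest (MSF) whose components are the
   basal modules of the network; completing it greedily to a Maximum
   Spanning Tree (MST) yields its global backbone. The degree profiles of
   these structures separate *chain-like* organization (nearly all degrees
   at most 2) from *star-like* organization (hubs), which is the scaffold
   signature this analysis was designed to detect.

All network stages operate on the pointwise-squared group correlation
matrix, $w_{ij} = r_{ij}^2$: squaring discards the (physiologically
ambiguous) sign of a correlation while preserving the ranking of
magnitudes, and $r^2$ coincides with the coefficient of determination of a
simple linear regression of one series on the other. `groupWeights()` also
exposes `r` and `abs_r` modes for sensitivity checks; thresholds found on
the $w$ scale are reported on the correlation scale as $\sqrt{w}$.

## Group averaging and inter-subject diagnostics

Per-subject correlation matrices (`pearsonMatrix()`) are combined with the
Fisher transform: each matrix is mapped through $z = \operatorname{atanh}
r$, averaged entrywise across subjects, and mapped back with $\tanh$
(`fisherAverage()`). Averaging on the $z$ scale keeps the group value
inside $(-1, 1)$ and treats correlations near $\pm 1$ on the correct
variance-stabilized scale; $|r|$ is clipped at $1 - 10^{-12}$ before
`atanh` to keep the arithmetic finite.

Two diagnostics guard against a single subject driving the group matrix.
`variabilityMaps()` reports the entrywise arithmetic mean, sample SD
(denominator $n-1$) and coefficient of variation of the raw correlations;
the CV is only defined on edges whose across-subject Fisher-z values differ
from zero (one-sample t-test, Benjamini–Hochberg FDR over all
$N(N-1)/2$ edges, default $q = 0.05$). Edges with mean near zero — the
ones with unstable CVs — are exactly the edges the mask removes, and they
play no role downstream, where only the largest weights matter. The test
statistic and $q$ are configurable because no single convention dominates
practice. `jackknifeSimilarity()` recomputes the group matrix with each
subject left out and reports the pairwise cosine similarities between the
leave-one-out matrices (strict upper triangles only, since the unit
diagonal would inflate similarity).

## Percolation and plateau significance

`percolate()` removes the $N(N-1)/2$ links in increasing weight order
(ties broken lexicographically by node pair, which makes runs reproducible;
component counts after a tie block are invariant to the order within it)
and records the component count after every removal. It is implemented as
the time reversal of a union-find aggregation, so the full curve costs
$O(M\,\alpha(N))$ rather than $M$ recomputations; an igraph flood-fill
oracle verifies the counts in the test suite.

`plateauLengths()` measures, for every transition from $n$ to $n+1$
components, the weight increment since the previous component birth. The
first birth has no predecessor; its plateau is measured from the minimum
edge weight of the graph, a convention that makes the lengths sum
telescopically to (last birth weight − minimum weight).

`selectThresholds()` flags real plateaux that exceed the null mean plus
`kSd` (default 4) standard deviations. Two comparison rules are provided:

* **matched** (default): the $m$-th real plateau is compared against the
  mean $+\,k\sigma$ band of the $m$-th plateau lengths across null curves —
  the pointwise confidence band along the percolation curve.
* **pooled**: every null plateau length is lumped into one distribution
  with a single global cutoff.

The matched rule is the default because plateau lengths are strongly
heavy-tailed *along* the curve: the last few component births happen in the
sparse upper tail of the weight distribution, where consecutive-weight gaps
are orders of magnitude larger than in the bulk. Under the pooled rule
every null curve's own terminal plateau exceeds the global cutoff (at
roughly 5–7 pooled SDs in our synthetic experiments), so the pooled test
loses all specificity; the matched rule compares tail against tail and bulk
against bulk, and in the same experiments 95–100% of null curves show no
significant plateau while the real curve retains its significant ones. The
pooled rule is kept as an option, and per-curve mean plateau lengths are
attached to the result for reporting.

`snapshotGraph()` materializes the network at a selected threshold (edges
with weight strictly below it discarded, all $N$ nodes retained); its
component partition provably matches the percolation state just before the
first removal at or above the threshold.

## The null ensemble

A valid benchmark for a correlation matrix must itself be a correlation
matrix. `fixedSpectrumCorrelation()` starts from
$A_0 = Q \Lambda Q^\top$ with $Q$ Haar-orthogonal (Gaussian matrix, QR
factorization, columns sign-corrected by $\operatorname{diag}(R)$ so the
distribution is exactly rotation invariant) and $\Lambda$ the observed
eigenvalues. $A_0$ is symmetric and PSD with the right spectrum but not
unit-diagonal; since its trace is $N$, while the diagonal is not all ones
there exist $a_{ii} < 1 < a_{jj}$, and a Givens rotation in the $(i,j)$
plane — an orthogonal similarity, hence spectrum- and PSD-preserving — can
set $a_{ii}$ to exactly 1. At most $N-1$ such rotations finish the job, so
no post-hoc "repair" that would distort the spectrum is ever needed.
Deterministic details: the scan picks the first deficient and first
excessive diagonal entry; of the two rotation angles that work, the one
with smaller $|\tan\theta|$ is used for numerical stability. Member $k$ of
an ensemble is seeded with `masterSeed*10000 + k`, making ensembles exactly
reproducible; the eigenvalue spectrum of the source matrix is clipped at
zero (tolerance $-10^{-8}$, matrices more indefinite than that are
rejected with advice to repair upstream) and rescaled by $N/\sum\lambda$ so
the trace-$N$ identity holds exactly. All real-versus-null comparisons use
the pointwise square of each member, mirroring the $r^2$ weighting of the
observed matrix.

## Spanning structures

`msfRowMax()` keeps, for each node, the arc to its maximally correlated
partner. Row ties are broken toward the smallest partner index — with
continuous weights ties have measure zero, so the rule only matters for
synthetic or degenerate inputs. `msfGreedy()` is the equivalent
construction from scratch (rank all weights decreasing; add a link if at
least one endpoint still has degree zero); the equality of the two
undirected edge sets on distinct-weight matrices is asserted as a property
in the tests.

`mstComplete()` adds the discarded weights in *decreasing* order under
union-find, merging components until one remains. Decreasing order is the
only choice under which the completed structure attains the maximum total
weight over all spanning trees, which is the defining property of an MST;
an independent Kruskal oracle (igraph, on negated weights) and an
exhaustive enumeration of all labelled trees via Prüfer sequences (for
$N \le 7$) certify optimality in the test suite. The tree has the standard
$N-1$ undirected edges ($2(N-1)$ if arcs were counted in both directions).

`degreeProfiles()` histograms the MSF in-degree (0 is possible and common
in star-like forests, despite every node having out-degree 1) or the MST
degree, and computes a *chain score*: the fraction of nodes with undirected
degree at most 2. A pure path scores 1; a star on $m \ge 4$ nodes scores
$(m-1)/m$ because of its hub.

## The synthetic cohort generator

`generateCohort()` makes every downstream claim testable without any data
download. A `cohortSpec()` plants a population correlation matrix with
modular structure: modules partition the ROIs; pairs adjacent in a module's
topology graph (chain neighbours, hub–leaf pairs, clique pairs, bilateral
pairs) get the full `rWithin` correlation, a within-module pair at topology
distance $d$ gets `rBetween + (rWithin − rBetween)·rWithin^(d−1)` — the
AR(1)-like geometric decay a chain of correlated signals actually exhibits,
and hub-mediated $r^2$ coupling for star leaves — and between-module pairs
get `rBetween`. Positive semidefiniteness is enforced by eigenvalue
clipping at zero plus diagonal renormalization; if the repair moves any
entry by more than 0.05 the requested levels are rejected with the
offending module named (the geometric-decay construction is PSD-consistent
by design, so this error is defensive).

Each subject's matrix is the planted one perturbed with i.i.d. Gaussian
noise on the Fisher-z scale — mirroring the group-averaging transform and
keeping perturbed values inside $(-1,1)$ — re-symmetrized, PSD-repaired,
and sampled for $T$ time points from a zero-mean multivariate normal
(eigendecomposition sampler, safe for semidefinite matrices). Pearson
correlation is the only statistic consumed downstream, so Gaussianity is a
modelling convenience, not an assumption the analysis depends on. Subject
$s$ is seeded with `seed*1000 + s`: cohorts are bitwise reproducible and
subject noise is independent across subjects.

The reference design, `defaultChainCohort()`, fixes the study conditions
used by the validation experiments: 8 chain modules of sizes 15, 11, 8, 7,
6, 5, 4 and 2 (58 ROIs, spanning bilateral pairs up to one long chain, the
range of component sizes strongest-link filtering of resting-state data
exhibits), 40 subjects, $T = 240$ time points, `rWithin = 0.6` (a strong
but realistic adjacent-region coupling after preprocessing),
`rBetween = 0.1` (weak background coherence) and `subjectNoiseSd = 0.1`
(inter-subject SD comparable to published across-subject variability of
edge correlations). These values were fixed once, when the generator was
designed, and are not tuning knobs.

What the generator does **not** emulate: hemodynamic autocorrelation,
physiological confounds, negative planted correlations (the analysis
squares weights, so only magnitudes matter downstream), non-Gaussian
marginals, and spatial structure of the parcellation. Passing recovery
tests therefore show that the pipeline's inference machinery is correct
under its own model, not that real BOLD data satisfy that model.

## Numerical choices, in one place

* $|r|$ clipped at $1 - 10^{-12}$ before `atanh`; weights compared exactly,
  ties broken lexicographically.
* Percolation, plateau and selection arithmetic is exact given the weight
  matrix; no tolerance enters until null bands are formed.
* Eigenvalues clipped at 0 when $\ge -10^{-8}$; spectra rescaled to trace
  $N$; spectrum preservation is verified to $10^{-8}$ per member.
* Degenerate inputs: constant ROI signals are rejected by name; all-equal
  weight rows are assigned an arc by the tie rule with a warning; empty
  stacks, undersized cohorts ($<3$ subjects for SD/jackknife) and non-PSD
  group matrices raise informative errors.
* Master seeds spawn member seeds by fixed arithmetic (`*1000 + s` for
  subjects, `*10000 + k` for null members), all reduced modulo
  $2^{31}-1$.

## Problem sizes used by the shipped experiments

The validation suite runs entirely on synthetic data: oracle equivalences
use 100–500 random matrices of 4–20 nodes; the null-validity check uses
100 members at $N = 50$; the recovery experiment runs 20 repetitions of
the 58-ROI default cohort with 20-member ensembles; the acceptance script
runs one repetition with the full 100-member ensemble. These sizes were
chosen so the complete suite documents the method's behaviour in minutes
on a laptop while exercising every code path at realistic dimensionality.

## Known limitations

* The MSF/MST scaffold is a point estimate; no edge-level uncertainty is
  propagated into the tree.
* The FDR mask's test family (all edges) and level are conventions; the CV
  diagnostic, not the core pipeline, depends on them.
* The pooled plateau-selection rule is provided for completeness but is
  not recommended (see above).
* Weight modes other than $r^2$ are sensitivity tools; the pipeline's
  defaults assume nonnegative weights.

## A minimal run

```{r example, eval = FALSE}
spec <- defaultChainCohort(seed = 7)
out <- file.path(tempdir(), "demo-run")
runPipeline(pipelineConfig(outputDir = out, spec = spec,
                           nNull = 100, masterSeed = 7))
reportSummary(out)
```
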