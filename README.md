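# NetScaffold

Threshold-free scaffold analysis of weighted correlation networks, built
for resting-state functional connectivity but applicable to any symmetric
correlation matrix. Given per-subject ROI time series, the package

- builds per-subject Pearson correlation matrices and a Fisher-averaged
  group matrix (`pearsonMatrix()`, `fisherAverage()`), with inter-subject
  variability and jackknife diagnostics (`variabilityMaps()`,
  `jackknifeSimilarity()`);
- runs a **component-tracking percolation**: links are removed one at a
  time in increasing weight order and the number of connected components
  is recorded after every removal (`percolate()`); runs with no change in
  the count are *plateaux*, whose lengths mark stable network
  configurations (`plateauLengths()`);
- calibrates plateau significance against an ensemble of random
  correlation matrices with **exactly the observed eigenvalue spectrum**,
  generated by a Haar-orthogonal similarity of the eigenvalue matrix plus
  Givens rotations that restore the unit diagonal
  (`ensembleGenerate()`) — symmetric, unit-diagonal and positive
  semidefinite by construction;
- selects the thresholds where real plateaux exceed the null mean plus
  4 SD bands (`selectThresholds()`) and materializes the network at those
  thresholds (`snapshotGraph()`);
- extracts the network's basal scaffold: the directed **Maximum Spanning
  Forest** keeping each node's single strongest link (`msfRowMax()`, with
  the equivalent greedy construction `msfGreedy()`), its completion into a
  **Maximum Spanning Tree** (`mstComplete()`), and the degree profiles
  that separate chain-like from star-like organization
  (`degreeProfiles()`).

All network stages operate on the pointwise-squared group matrix
`w_ij = r_ij²`, which neglects correlation signs while preserving the
ranking of magnitudes; thresholds are reported on both the `w` and the
`r = √w` scale.

A synthetic cohort generator (`cohortSpec()`, `generateCohort()`) plants
modular, chain-like, bilaterally paired correlation structure with
subject-level Fisher-z noise, so the whole pipeline is testable end to end
without any data download.

## Worked example

Simulate the reference cohort (8 chain modules over 58 ROIs, 40 subjects,
240 time points), run the full pipeline with a 100-member null ensemble,
and summarize:

```r
library(NetScaffold)
spec <- defaultChainCohort(seed = 7)
out <- file.path(tempdir(), "demo-run")
runPipeline(pipelineConfig(outputDir = out, spec = spec,
                           nNull = 100, masterSeed = 7))
reportSummary(out)
```

```
MSF: 20 components (sizes 6,4,4,4,3,3,3,3,3,3,3,3,2,2,2,2,2,2,2,2), 20 reciprocated pairs
MSF max in-degree 2, chain score 1.000
Selected thresholds (n=1): w = 0.0201 | r = 0.1419
MST total weight 13.3551, max degree 4; hubs: ROI44(4) ROI45(4) ROI24(3) ROI28(3) ROI36(3)
Max plateau: real 0.2172 vs null 0.0807
```

Reading the output: the strongest-link filter breaks the 58-ROI network
into 20 loop-free components, all of them chains or mutual pairs (chain
score 1.000, no node receives more than 2 arcs) — the planted chain
modules, fragmented where subject noise weakens a link. One percolation
plateau (length 0.217) stands far above anything the spectrum-matched
randomizations produce (longest null plateau 0.081), and its starting
weight 0.0201 (correlation 0.142) is the significant threshold separating
the modular regime from the between-module background. The completed tree
spans all ROIs with maximal total weight 13.36 and hubs of degree at most
4, i.e. it remains chain-like; randomized matrices instead give star-like
forests (typical max in-degree ≈ 5 at this size, with half the nodes at
in-degree 0).

The run directory holds every artifact as delimited text (group matrices,
percolation curve, plateau table, thresholds, MSF arcs and component
summary, MST edges, degree histograms, the null ensemble with its
spectrum hash) plus GraphML exports and a machine-readable `report.json`.
Reruns with the same configuration are byte-identical. Pipelines can also
be driven by a YAML file (`runPipeline("config.yaml")`) or fed measured
data through a cohort manifest (`writeCohort()` / `readCohort()`, one
delimited time-series file per subject).

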