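---
title: "Deriving and applying cell-type signatures from bulk co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and applying cell-type signatures from bulk co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigweave)
```

## The model behind the method

A bulk tissue biopsy is, to a first approximation, a convex mixture of the
expression programs of the cell types and anatomical structures it contains.
If a gene is expressed specifically by one population, its measured
abundance in a sample tracks that population's mixing proportion; across a
cohort of biopsies whose composition varies — by sampling site, depth, or
biology — all markers of the same population therefore rise and fall
together. sigweave turns that observation into a derivation pipeline:

1. **Co-expression network.** Compute all pairwise gene–gene Pearson
   correlations and keep edges with $r \ge t$ (inclusive). Correlation is
   computed on $\log_2(x + 1)$ values for linear-scale input by default,
   because expression noise is approximately multiplicative and a handful
   of very highly expressed genes would otherwise dominate the covariance.
   The threshold is the key tuning parameter: the package exposes it per
   platform, and `permutation_null()` quantifies how improbable the
   retained edges are by independently permuting each gene across samples
   and recounting edges at the same threshold.
2. **Markov clustering.** Partition the weighted graph with MCL at
   inflation 2.2. MCL simulates flow on the graph by alternating expansion
   (matrix squaring of the column-stochastic flow matrix) and inflation
   (element-wise power followed by column renormalisation) until the flow
   collapses onto disjoint attractor systems; inflation controls
   granularity, with higher values fragmenting the graph into more, smaller
   clusters.
3. **Cross-platform matching.** Repeat steps 1–2 on a second, independent
   cohort measured on a different platform, restrict both to the common
   gene universe, and match clusters across the two analyses. Each matched
   pair's *intersection* becomes a signature — a deliberately conservative
   marker set containing only genes that co-cluster in both datasets.
4. **Application.** Score each signature in a disease or condition cohort
   as the mean $\log_2$ expression of its genes per sample, compare test
   and control groups by the score difference (a log fold change), and
   assess significance with a self-contained rotation gene-set test. A
   signature is called significantly altered only when its BH-adjusted
   p-value is at most 0.01 **and** at least 80% of its genes move in the
   same direction — the concordance condition withholds significance from
   sets whose mean shifts on the strength of a minority of genes.

A positive signature fold change in a condition reads as
overrepresentation of that population in the test biopsies; the flip side
is the *dilution effect*, where an influx of one population (immune cells,
typically) depresses every other resident signature without any per-cell
repression.

## The synthetic study generator

The package ships a generator that produces exactly the data-generating
structure the method assumes, with known ground truth, so every stage is
testable without external downloads:

* `generate_profiles()` builds cell-type base-expression profiles with
  disjoint designated markers (own-type mean `hi_mean = 500`, cross-type
  `lo_mean = 5`, minimum fold separation 8 — a strongly but not absurdly
  specific marker). Housekeeping genes get one log-uniform mean each with a
  fixed per-type multiplicative jitter of $\sigma = 0.05$, so they
  correlate strongly with nothing.
* `generate_cohort()` draws per-sample proportions from a Dirichlet law
  (default concentration 5 per type — compositions vary enough to induce
  detectable marker co-expression while staying realistically mixed; this
  is the generator's "signal strength" dial), mixes the profiles, applies
  per-(gene, sample) multiplicative log-normal noise (default
  $\sigma = 0.15$ on the natural-log scale, a mid-range value for
  RPKM/intensity replicate noise), and for array-like platforms clips the
  signal at a saturation cap (default 16 000, where microarray probe
  response visibly plateaus). Platforms also differ by gene universe
  (default 85% overlap), reproducing the common-symbol filtering setting.
* `generate_condition_pair()` multiplies one cell type's Dirichlet
  concentration in the case cohort, which raises its expected proportion
  and necessarily dilutes all others — the influx phenomenon.
* A Dirichlet concentration of exactly 0 means "absent", which is how the
  signature-splitting fixtures plant a disease-linked expression program
  present only in case samples.

What the generator does **not** emulate: count-level (negative binomial)
sampling noise, batch effects beyond the platform transform, correlated
marker programs shared between cell types, probe-level effects other than
saturation, and compositional outliers. Passing tests therefore demonstrate
that the pipeline recovers planted mixture structure under realistic noise;
they do not certify performance on real biopsies, where marker specificity
is imperfect and cluster annotation requires expert review.

## Numerical and design choices

* **Correlation storage.** All-pairs correlations are held as a condensed
  upper triangle keyed by sorted gene order ($n(n-1)/2$ doubles) and
  computed in row blocks, so the 15k-gene scale stays within laptop
  memory. Values within $10^{-12}$ of $\pm 1$ are snapped to $\pm 1$: at
  double precision they are indistinguishable from exact collinearity, and
  snapping makes the inclusive threshold $r \ge 1$ behave. Constant genes
  are excluded (their correlation is undefined), never assigned $r = 0$.
* **MCL details.** Self-loops are added with weight equal to the node's
  maximum incident edge weight (standard practice; keeps the random walk
  from oscillating). Edge weights are the raw Pearson $r$ values, not
  binarised. Pruning (default $10^{-5}$) always retains each column's
  maximum entry so no node loses all flow; convergence is declared when
  the largest element change drops below $10^{-6}$, capped at 100
  iterations (non-convergence returns the current clustering with a
  warning flag). Cluster membership ties are broken by the
  lexicographically smallest attractor gene ID, making output independent
  of node insertion order.
* **Cluster matching.** The original derivation matched clusters across
  datasets by manual annotation; sigweave automates that step as
  best-reciprocal hypergeometric matching within the common universe
  (defaults: minimum cluster size 5, Jaccard ≥ 0.1, BH FDR ≤ 0.01). The
  thresholds are exposed because the right stringency depends on cluster
  granularity.
* **Overlap summaries.** Percentages are rounded half away from zero to
  integers, matching how such tables are printed, and the mean ± SD
  summary is computed over the rounded values (the unrounded variant is
  also reported). This choice makes the summary exactly recomputable from
  a printed table.
* **Probe collapse.** For derivation, the single probe with the largest
  median absolute deviation represents its symbol (most informative
  probe); ties go to the lexicographically smallest probe ID for
  determinism. For application/scoring, probes are averaged by per-sample
  geometric mean; linear values below $10^{-6}$ are floored first so zeros
  never produce $-\infty$. Geometric-mean collapse requires linear input —
  the geometric mean of signed log values is ill-defined.
* **Scoring.** Linear input is transformed as $\log_2(x + 1)$ (the RPKM
  convention; the pseudocount is configurable). Signature genes absent
  from a matrix are dropped with the coverage fraction recorded, rather
  than imputed — the normal situation when applying a catalog across
  platforms. Group fold changes difference per-sample score means; for the
  two-group designs supported the per-sample-first and per-group-first
  forms coincide.
* **Rotation test.** The set statistic is the unweighted mean of per-gene
  moderated t statistics (residual variances optionally shrunk toward the
  across-gene mean with prior weight 4). The null is generated by random
  unit directions in the (effect + residual) space of the two-group
  design. Two implementation details are worth knowing: the orthonormal
  basis is built from a label-free indicator over canonically ordered
  samples, and rotations are drawn in antithetic ± pairs — together these
  make the exchange symmetry exact (swapping test and control labels
  swaps `p_up` and `p_down` to the last bit) rather than merely
  distributional. P-values use the add-one estimator
  $(1 + b)/(1 + B)$ and can never be exactly zero; the default 9999
  rotations (rounded up to 10 000 pairs-inclusive) put the floor at
  $10^{-4}$, comfortably below the 0.01 FDR threshold.
* **Multiplicity.** BH adjustment is applied across the signature family
  within one comparison; the derivation this package follows did not name
  a procedure, so the choice is documented here rather than attributed.
* **Signature splitting.** The sub-network is rebuilt on the signature's
  genes only, clustered with the same MCL settings, and the two largest
  clusters are labelled up/down by the sign of their mean log fold change
  in the designated comparison. The sub-network threshold is not dictated
  by the method description, so it defaults to the caller's derivation
  threshold and is exposed. If fewer than two clusters of size ≥ 2 emerge
  the function reports "no split" instead of fabricating subgroups.
* **Pipeline reproducibility.** One global seed deterministically derives
  a seed per stage from the stage name, so any stage can be re-run in
  isolation; outputs are plain TSV/GMT with a JSON manifest of parameters
  and content hashes, and unchanged stages are skipped on re-runs.

## Problem sizes used by the test suite

Verification runs at two scales, chosen to exercise the claimed behaviour
while keeping the default suite fast: unit fixtures use a few hundred genes
and 60–120 samples, and the end-to-end property checks use the full
study-shaped configuration — 8 cell types × 25 markers among 2000 genes,
150 samples per platform, noise σ = 0.15, threshold r ≥ 0.70 — plus 1000
null simulations (20-gene sets, 10 vs 10 samples) for the rotation-test
calibration. The `scripts/acceptance.R` entry point re-runs the same
computations from scratch and writes the resulting quantities as JSON.

## Known limitations

* Only two-group contrasts are supported in the set test; covariates,
  paired designs, and competitive (between-set) tests are out of scope.
* MCL here is the canonical weighted iteration; regularised or multilevel
  variants, and soft/overlapping cluster output, are not implemented.
  External tools expose scheme parameters that can change exact cluster
  counts on real data, so cluster counts are not comparable across
  implementations — the package's tests therefore validate against a
  step-by-step reference execution and against planted ground truth, not
  against any tool's cluster numbering.
* Signature naming is left to the user (or auto-generated); no enrichment
  analysis is bundled, and the biological annotation step that a real
  derivation requires has no automated substitute.
* The expressed-gene filter and the common-universe restriction both
  assume linear-scale input with comparable normalisation across samples;
  the package does not perform array preprocessing, batch correction, or
  between-sample normalisation.
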