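---
title: "Diverse cluster ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diverse cluster ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EnsembleClust)
```

## The problem

Class discovery in high-dimensional profiling data — finding tumour
subtypes in expression matrices is the motivating case — forces three
subjective choices on the analyst: which clustering algorithm to trust,
which number of clusters `k` to request, and how to decide whether the
resulting partition reflects real structure rather than the inevitable
output of an algorithm that always returns *some* partition. No single
algorithm wins in general, different algorithms disagree, and several
groupings can be consistent with the same data.

This package addresses all three choices with a cluster ensemble. Many
base clusterings ("experts") are generated by varying the algorithm, the
distance metric, the requested `k` and the subset of observations; the
array of clusterings is then combined into consensus partitions, the
cluster number is selected from a stability statistic rather than by eye,
poorly performing algorithms are voted out by the data, and the final
split is subjected to a significance test against a one-cluster null.

## Diverse generation

`generateArray()` applies every configured algorithm at every `k` to
repeated random subsamples containing 80% of the observations. The
subsample fraction is the framework's defining perturbation: a pair of
samples that only co-clusters in some subsamples is evidence of an
unstable boundary. The subsample size is `round(fraction * n)`; with the
default fraction 0.8 and `n = 100`, every repetition clusters exactly 80
samples. The default of 10 repetitions keeps runs-per-(algorithm, k) large
enough for stable co-clustering proportions without dominating runtime.

The ten built-in base algorithms (`builtinAlgorithms()`) deliberately span
model families: k-means, PAM, three agglomerative linkages (average,
complete, Ward), divisive hierarchical (DIANA), spectral clustering, a
Gaussian mixture, fuzzy c-means hardened by largest membership, and a
self-organising map whose codebook is partitioned by k-means. Distance
based algorithms consume one of four metrics (Euclidean, Manhattan,
Pearson and Spearman dissimilarity `1 - cor`); the registry is open, so a
user-supplied `algorithmSpec()` slots in beside the built-ins. Each run
draws its own RNG stream from a hash of (seed, repetition, algorithm, k),
so results are reproducible and unaffected by adding or removing other
algorithms. A failing run (singular fits do happen) is logged and leaves
its slice missing instead of aborting the ensemble — an ensemble should
tolerate the failure of individual experts.

Samples outside a repetition's subsample are *completed* by
`completeByKNN()`: a missing sample takes the majority label of its 5
nearest assigned neighbours (Euclidean distance in the prepared feature
space, regardless of the base algorithm's own metric), ties to the
smallest label. Completion is idempotent, and is the identity when the
fraction is 1.

## Consensus formation

One `k`-slice of the completed array is a samples × runs label matrix.
Four combiners are implemented (`consensusMethods()`):

* **Majority voting.** Cluster IDs are arbitrary across runs, so each run
  is first aligned to a reference run by solving the linear assignment
  problem on the contingency table (`relabelPartition()`, Hungarian
  method); each sample then takes its modal label. The reference is the
  first run by default and is configurable.
* **k-modes.** Each sample's vector of run labels is treated as
  categorical data and clustered directly: simple-matching dissimilarity,
  per-position-majority mode updates, seeded initial modes drawn from
  distinct rows. Because the objective has local minima, the default
  keeps the best of 20 seeded starts by total matching cost.
* **CSPA.** The co-clustering proportion matrix is used as a similarity;
  samples are partitioned by average-linkage hierarchical clustering of
  `1 - consensus`, cut at `k`. The original formulation partitions a
  similarity graph with METIS; the hierarchical cut was chosen here for
  determinism and freedom from an external solver, and is flagged
  degenerate when the dendrogram offers no separation at the cut.
* **LCE.** Link-based refinement: clusters from all runs become nodes
  scored by shared membership (Jaccard), similarity is transmitted
  through common neighbour clusters (weighted connected triples,
  normalised to the largest triple weight), and each sample's association
  to every non-member cluster is `dc` times its best link, with decay
  constant `dc = 0.8` by default. Samples are then clustered on their
  association rows. At `dc = 0` the association matrix collapses to
  binary membership.

All four are invariant to within-run label permutations and equivariant
under sample reordering, and reproduce a partition that all runs agree on
— these invariances are enforced by tests.

## Choosing k and judging stability

`consensusMatrix()` records, for every sample pair, the proportion of
runs clustering them together among runs assigning both. Entry
provenance (numerator and denominator counts) is kept so that
pre-completion matrices with never-co-sampled pairs mark those entries
undefined rather than zero.

The empirical CDF of the off-diagonal consensus entries summarises
stability: a clean clustering puts nearly all mass at 0 and 1. The area
under this CDF and its relative change across `k` (`deltaAUC()`; the area
of a step CDF on `[0, 1]` is exactly `1 - mean(values)`) reproduce the
familiar consensus-clustering diagnostics. The **proportion of ambiguous
clustering** (`pac()`) is the fraction of entries strictly inside an
ambiguity interval, `(0.05, 0.95)` by default; the interval is open, so
entries exactly at a bound count as unambiguous — the literature is
silent on the boundary, and this dialect choice is documented rather than
assumed. `selectK()` picks the `k` with the smallest PAC, ties to the
smallest `k`.

## Validity indices, trimming and weighting

`internalIndices()` scores a partition with thirteen indices:
Calinski-Harabasz, Dunn, PBM, tau, gamma, C-index, Davies-Bouldin,
McClain-Rao, the SD dispersion component, Ray-Turi, G-plus, mean
silhouette width and compactness, each tagged `maximize` or `minimize`.
The concordance-based indices count the pairs `(w, b)` of one
within-cluster and one between-cluster distance with `w < b` (`s+`) and
`w > b` (`s-`); tau is `(s+ - s-)` over the number of comparable pairs,
gamma is `(s+ - s-)/(s+ + s-)`, and G-plus is `2 s- / (Nd (Nd - 1))` with
`Nd = n(n-1)/2` total distances. Indices undefined for a partition
(single cluster, zero-diameter clusters) are returned as flagged
non-values, never errors, and every downstream consumer skips them.

`rankAlgorithms()` aggregates the per-index rankings either by Borda
(mean rank, deterministic, the default) or by a seeded Monte-Carlo search
for the ordering with minimal total Spearman footrule distance to the
index rankings; on small problems the search provably reaches the
exhaustive optimum (tested). Trimming to the top `N` algorithms is
decided once across all `k`: each algorithm is represented, per index, by
its best score over the `k` range. The alternative — trimming separately
per `k` — would let different `k` see different ensembles and make the
PAC comparison across `k` incoherent, which is why the once-for-all rule
was adopted. Optional weighting (`computeWeights()`) min-max rescales
each index column (flipping minimise columns), averages over defined
indices, and normalises; the weighted consensus matrix then weighs every
run by its algorithm's weight. Weights use internal indices only —
reference labels, when present, are reserved for external validation
(ARI, NMI, accuracy after Hungarian relabelling) and never influence the
ensemble itself.

## Significance testing

`sigclust()` asks whether the best two-way split is tighter than expected
had the data been a single Gaussian. The statistic is the cluster index
`CI = within-SS / total-SS`, minimised over splits by 2-means (20 seeded
restarts; minimising CI and minimising the 2-means objective coincide
because the total SS is fixed). The null covariance is diagonal in the
eigenbasis: sample-covariance eigenvalues floored at the background noise
variance `(MAD of centred values / 0.6745)^2` — the hard-flooring
variant; soft thresholding is out of scope. With `nSim` simulated null
datasets the p-value is the add-one estimator
`(1 + #{null CI <= observed CI}) / (1 + nSim)`, which cannot report an
exact zero. `significanceDriver()` applies the test top-down: once to the
full data and once inside each sufficiently large final cluster,
reporting raw p-values without multiplicity correction (the sequential
traversal is a reporting convenience, not a formal selective-inference
procedure, and is documented as such).

Calibration has a dimensionality caveat worth knowing: when `p/n` is not
small, sample eigenvalues are overdispersed, the simulated null splits a
little too easily, and p-values skew high — the test becomes
conservative. The test suite verifies near-uniform null p-values at
`n = 150, p = 2` (Kolmogorov-Smirnov statistic below 0.15 over 200
replicates) and verifies the conservative regime only through its safe
consequence: on `n = 100, p = 5` null data at least 90 of 100 replicates
give `p > 0.05`.

## The synthetic test-bed

`simulateMixture()` draws spherical Gaussian blobs at centres placed on a
rescaled regular simplex (all pairwise centre distances equal to the
requested separation) plus optional pure-noise features, with labels in
generation order; `simulateNull()` draws a single Gaussian. The study
fixture used by the recovery tests and the acceptance script is three
blobs of 50 samples in 10 features with centres 10 within-cluster
standard deviations apart — unambiguous geometry by design: it verifies
that the machinery is correct, not that the method is powerful. Passing
on it says nothing about marginal separations, non-spherical covariance,
heavy tails, or the feature correlations of real expression data; the
spherical within-cluster covariance is a deliberate restriction that
keeps every internal index's qualitative ordering predictable.

Problem sizes in the test suite (fixtures of 20–150 samples, 10
repetitions, `k` up to 6, 40–100 null simulations per significance test,
200 calibration replicates) were chosen so the full suite completes in a
few minutes on one core while still exercising every code path at the
study conditions stated above.

## Numerical and degenerate-input policy

* Missing input values are an error unless median imputation is
  requested; constant features are dropped (with a warning) only under
  scaling, where they are undefined.
* All tie-breaks are deterministic and documented: modal votes and
  k-modes updates take the smallest label, PAC bounds are open, Borda
  ties are alphabetical, `selectK` ties take the smallest `k`.
* Degenerate consensus solutions (fewer than `k` non-empty clusters, or
  a separation-free dendrogram cut) carry a `degenerate` flag instead of
  erroring, so the pipeline can skip them in evaluation.
* Completion refuses a slice with no assigned samples unless explicitly
  told to skip it; the `dice()` driver skips, then drops those runs from
  the label matrices.
* Correlation dissimilarities clamp tiny negative rounding residues to
  zero; covariance eigenvalues are clamped at zero before flooring.
* Per-run seeds come from a string hash of the run coordinates, so any
  subset of the ensemble is reproducible in isolation.

## A worked run

```{r example, eval = FALSE}
fx <- simulateMixture(c(50, 50, 50), nFeatures = 10, centers = 10, seed = 1)
res <- dice(fx$data, kValues = 2:6, seed = 1, referenceLabels = fx$labels)
res
pacScores(res)
externalIndices(clusterLabels(ensembleSolutions(res)$LCE), fx$labels)
```

On this fixture the PAC curve is minimised at `k = 3` and all four
consensus methods recover the generating partition exactly (ARI 1); the
`scripts/acceptance.R` script in the source repository reruns this
computation from scratch together with the significance calibration.

## Known limitations

* CSPA uses a hierarchical cut rather than graph partitioning; on highly
  unbalanced consensus matrices METIS-style partitioners can differ.
* LCE follows the connected-triples formulation with Jaccard base
  similarity; no claim of bit-compatibility with other implementations
  is made, and the decay constant is a tuning parameter.
* Trimming across all `k` (not per `k`) and the first-run voting
  reference are conventions; both are configurable at the function level.
* The significance driver reports raw sequential p-values; correcting
  for the selection inherent in testing data-derived clusters is out of
  scope.
* No omics-specific normalisation is provided; the pipeline expects an
  already-normalised samples × features matrix.
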