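---
title: "Methods: molecular subtype discovery, verification and transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular subtype discovery, verification and transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisSubtypes)
```

This vignette is the package's own account of the statistical machinery: the
models and procedures, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
the numerical choices, and the known limitations.

## The problem and the model

The package targets bulk expression cohorts of septic ICU patients —
genes × samples matrices of normalized log2 intensities, with missing
entries, a curated list of disease-relevant candidate genes, and a clinical
attribute table per sample. The working hypothesis is that the cohort is a
mixture of a small number of molecular subtypes: for some subset of genes,
a sample's expected expression depends on its latent subtype, so those genes
are bimodally distributed across the cohort while the remaining genes are
uninformative. Discovery asks for the number of subtypes, the sample
assignments, and the gene set that carries the distinction; validation asks
whether the partition is a property of the biology or of the algorithm; and
transfer asks whether the learned model reproduces the same structure in an
independent cohort.

## Discovery pipeline

`discover_subtypes()` runs three stages, each logged with its gene count,
cluster sizes and average silhouette width.

**Stage A — candidate restriction and choice of k.** The matrix is
restricted to the curated candidate list (`restrict_to_gene_list()`, which
silently drops list members absent from the platform and reports the
requested/found counts). `select_k()` draws `floor(G/3)` genes without
replacement, clusters the samples at every k in `k_range`, records the k
with the highest average silhouette width, and repeats `n_reps` times; the
modal winner is chosen, with ties to the smaller k at both levels. The vote
runs once with PAM on Euclidean distance and once with Ward hierarchical
clustering on Minkowski distance. Requiring agreement between two algorithms
with different inductive biases (medoid-based partitioning versus variance-
minimising agglomeration) and different geometries guards against structure
that only one algorithm can see. If they disagree, the PAM choice wins and a
warning is raised, since PAM defines the rest of the pipeline.

**Stage B — enrichment tally.** `enrich_genes()` repeats, `n_outer` times:
draw `n_inner` random thirds, PAM-cluster each at k, and give every gene of
the best-silhouette third one tally point. The `top_m` most frequently
winning genes form the enriched subset (count-descending, lexicographic
tie-break), and PAM on that subset yields interim labels. The nested
`n_outer × n_inner` reading of the procedure is one of two defensible
readings of its description; both counts are exposed so the flat reading
(`n_inner = 1`) is also runnable.

**Stage C — genome-wide SAM and final clustering.** The interim labels are
a hypothesis about sample grouping; to let genes outside the curated list
join the signature, `sam_two_class()` scores the *complete* platform
against them. The final feature set is the q = 0 selection, the final PAM
run on it fixes labels, and the medoid expression vectors over the final
feature set constitute the transferable `subtype_model`.

Two caveats are inherent to this design and worth stating plainly. First,
Stage C tests labels that were derived from the same expression matrix, so
the SAM q-values at this step are not face-value error rates — selection
circularity inflates them in the optimistic direction, and on pure-noise
cohorts the pipeline can still produce a non-empty q = 0 set with a
respectable-looking silhouette. `discover_subtypes()` therefore warns
whenever the final average silhouette is below 0.15, and the bootstrap /
bimodality / PCA verification layer, run on the *final* solution, is the
intended guard: spurious structure is unstable under resampling and leaves
gene distributions unimodal. Second, clustering algorithms always return
clusters; the package's verification functions quantify, but cannot fully
remove, the risk that a partition is an artifact.

## Core primitives and conventions

* **Distances** (`distance_matrix()`): samples are the objects, genes the
  coordinates; Euclidean for PAM and the bootstrap, Minkowski for the
  hierarchical cross-check. The Minkowski exponent defaults to p = 3: p = 2
  would silently reduce the "different similarity measure" to Euclidean,
  defeating the purpose of the cross-check. It is configurable.
* **PAM** (`pam_cluster()`): classic BUILD+SWAP k-medoids via
  `cluster::pam`. The SWAP phase accepts strictly cost-decreasing exchanges
  until none exists, so the cost is non-increasing and termination is
  guaranteed; like any single-start local search it can in principle stop
  at a non-global medoid set on unstructured data, which the test suite
  documents by checking exact agreement with exhaustive search on small
  *structured* instances and the lower bound everywhere.
* **Hierarchical clustering** (`hier_cluster()`): Ward's criterion through
  the Lance–Williams `ward.D2` update, tree cut to exactly k, labels
  renumbered by first appearance.
* **Silhouettes** (`silhouette_widths()`): `s = (b − a)/max(a, b)` with two
  standard conventions made explicit — singletons score 0, and coincident
  points (a = b = 0) score 0. Implemented in the package so the conventions
  are owned and unit-tested; the `cluster` implementation serves as an
  independent cross-check in the tests.
* **Determinism**: every stochastic routine takes a seed; pipeline stages
  derive per-stage seeds from the master seed; assignment and argmax ties
  break to the lowest index / smallest k.

## SAM

For gene *i* with class means `x̄₁, x̄₂`, within-class sums of squares and
class sizes `n₁, n₂`, the moderated statistic is
`d = (x̄₂ − x̄₁) / (s + s0)` with pooled standard error
`s = √[(1/n₁ + 1/n₂)(SS₁ + SS₂)/(n₁ + n₂ − 2)]`. The exchangeability
constant `s0` is chosen by the coefficient-of-variation rule: over the
percentile grid 0, 5, …, 100 of `s`, pick the candidate that minimises the
CV of the median absolute deviation of `d` across ~100 `s`-quantile
windows (a fixed `s0`, including 0, can be supplied instead). The null
distribution comes from class-label permutations — exhaustively enumerated
when `choose(n, n₁)` is within the permutation budget, otherwise uniformly
sampled. For each gene's own `|d|` threshold the false-discovery estimate
is `π̂₀ · median_b(#{|d*_b| ≥ t}) / #{|d| ≥ t}`, with
`π̂₀ = min(1, 2·mean(|d| ≤ median null |d|))`; q-values are minimised over
all less-stringent thresholds, so they are non-decreasing as `|d|` falls,
and tied `|d|` share a q-value. "q = 0" is the final selection rule: the
median permutation produces no call at that gene's threshold. With a finite
permutation budget, q is a granular quantity and 0 is its attainable floor;
on a true null (random labels) the q = 0 fraction stays within the 0.005
type-I bound asserted in the tests.

## Verification layer

**Bootstrap co-clustering** (`bootstrap_stability()`): default 200
resamples with replacement, Ward/Euclidean clustering of each resample's
unique samples cut at k, and per-pair proportions of co-clustering among
co-drawn resamples. Two genuinely distinct subtypes put within-pair
proportions near 1 and between-pair near 0. Euclidean distance is used
here, and Minkowski in the main hierarchical cross-check — each where the
reference workflow used it. Resamples with at most k unique samples are
skipped and counted.

**Bimodality index** (`bimodality_index()`): a two-component,
common-variance Gaussian mixture fit by EM; `BI = √(π(1−π))·Δ` with
standardised separation `Δ = |μ₁ − μ₂|/σ`. The 1.1 threshold is the
conventional level above which two modes are evident in a density plot.
Numerical choices: the data are standardised before fitting (the index is
affine-invariant; doing so makes the EM, including its stopping rule,
exactly so), 10 starts (one quantile-based, the rest random pairs of
observations), at most 500 iterations, and an *absolute* log-likelihood
tolerance of 1e-8 — near the symmetric saddle the per-iteration gain can be
tiny long before the maximiser, so a relative rule stops too early.
Degenerate fits (vanishing component or variance) are discarded;
zero-variance input returns BI 0, unconverged. At Δ ≲ 1 the maximum-
likelihood estimate of BI itself has sampling error well above 10% even at
n = 5000 — a property of the estimand, not the optimiser (fits match or
beat `mclust`'s equal-variance model in log-likelihood) — so calibration
should be judged at clear separations.

**PCA** (`pca_separation()`): samples as observations, gene-wise centring,
no scaling; reports the PC1 variance fraction, scores and the BI of the
scores. Labels are echoed for plotting but never affect the decomposition.

## Signature extraction and transfer

`extract_coexpressed()` clusters genes on unsigned correlation distance
`1 − |r|` (Ward), cuts the tree at every module count in 2..10, scores each
module by the mean absolute standardised between-subtype difference of its
members, and returns the single best module if it clears `min_contrast`
(default 1.0 within-subtype SDs). The unsigned distance is deliberate:
subtype-driven genes shift in both directions, and a signed distance
splits one biological axis into two anti-correlated modules; unsigned
co-expression keeps them together, which is what makes the result a
signature of the subtype axis. Per-cohort signatures are merged by
order-stable intersection (`intersect_signatures()`), mirroring the
derivation-then-validation workflow.

`classify_by_medoid()` restricts a new cohort to the model's signature
genes and assigns each sample to the Euclidean-nearest medoid (ties, a
probability-zero event on continuous data, go to subtype 1). Silhouettes
are recomputed on the new cohort's own distances, so the reported average
is an honest measure of how well the transferred structure fits; on matched
synthetic pairs it tracks the derivation value to within 0.1.

## Downstream statistics

`compare_clinical()` uses the two-sided Fisher exact test for binary
attributes and the pooled-variance Student t-test (Welch by flag) for
continuous ones; degenerate attributes (single level, or zero variance with
equal means) report p = 1 with a note rather than an error. `fold_changes()`
reports `2^(mean₁ − mean₂)`, subtype 1 over subtype 2, direction stated in
the headers; swapping labels maps each fold change to its reciprocal.
`overrepresentation()` is the upper-tail hypergeometric test against a
user-supplied universe (default choice in practice: the platform's gene
list) with Bonferroni correction over the number of sets tested — the
statistical form of a pathway over-representation analysis, with annotation
sets supplied as GMT files rather than fetched from any service.

## The synthetic generator

`generate_cohort()` draws: two latent subtypes with proportion π (default
0.4, matching a 21/34-style split); signal genes as two-component Gaussian
mixtures with means `delta` within-subtype SDs apart (population
`BI = √(π(1−π))·delta`), shift direction random per gene so both over- and
under-expressed signature genes occur; noise genes as a single Gaussian;
baselines around 8 log2 units; missing-at-random entries, plus optional
samples forced above the 80% missingness filter threshold (85% masked);
binary and continuous clinical attributes with per-subtype parameters
(severe sepsis 36% vs 9% by default, per-subtype means with user-set SDs
for age, length of stay and APACHE II, since only means are anchored);
and a curated candidate list containing 90% of the signal genes plus an
equal number of decoy noise genes. Defaults mirror the reference design:
55 derivation samples, 365 candidate genes, ~10% signal, delta = 3;
derivation missingness 1% and validation 5% — the derivation rate is a
free choice, the higher validation rate reflects that cohort's documented
noisier profiling. `generate_cohort_pair()` shares the gene-level draws
between a derivation and a validation cohort so that transfer is
well-posed. Everything is deterministic given the spec and seed.

What the generator does *not* emulate: probe-level effects, batch and dye
bias, correlated noise between genes beyond the subtype factor, non-MCAR
missingness mechanisms, and transitional patient states lying between
subtypes. Passing tests on synthetic cohorts therefore demonstrate
correctness of the machinery and recoverability under the stated mixture
model, not performance on any real cohort.

## Problem sizes used in the tests

The defaults (100 repetitions, 100 × 100 tally, 200 permutations, 200
bootstrap resamples) are the reference settings; the test suite and the
acceptance script exercise the same conditions (delta = 3, n = 55, 365
genes, 10% signal, proportion 0.4) at reduced repetition counts — e.g.
50 k-selection repetitions, a 25 × 25–40 tally, 100–200 permutations —
chosen once as sizes at which every property under test is already stable.

## Known limitations

* Stage-C q-values are conditioned on data-derived labels (see above); the
  verification layer is the guard, not the q-values themselves.
* PAM is a local search; global optimality is guaranteed neither in theory
  nor, on unstructured data, in practice.
* The bimodality index is hard to estimate at small separations.
* Gene-median imputation is simple and deterministic but ignores
  inter-gene correlation; pairwise-complete distances are a reasonable
  alternative the package does not currently implement.
* The package assumes pre-normalized log2 input; no background correction,
  normalization or probe-to-gene collapsing is performed.
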