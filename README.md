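# sepsisSubtypes

Unsupervised discovery and validation of molecular subtypes in
gene-expression cohorts of critically ill septic patients.

Sepsis is a syndromic diagnosis: broad clinical criteria group together
patients whose underlying biology may differ substantially, which is one
candidate explanation for the stream of negative sepsis trials. This package
implements a complete subtype-discovery workflow for microarray-style
log2-intensity expression matrices (genes × samples): it asks whether a
septic cohort splits into molecularly distinct groups, extracts the gene
signature that defines the split, verifies that the split is real rather
than an artifact of clustering, transfers the subtype model to an
independent cohort, and compares clinical attributes and pharmacogene
expression between subtypes.

## The method

Discovery is a three-stage feature-selection-and-clustering procedure built
on partitioning around medoids (PAM, k-medoids with Euclidean distance) and
average silhouette width
`s(i) = (b(i) − a(i)) / max(a(i), b(i))`,
where `a(i)` is a sample's mean within-cluster distance and `b(i)` its
smallest mean distance to another cluster:

1. **Candidate restriction and cluster number.** The platform is restricted
   to a curated sepsis-related gene list. The number of clusters *k* is
   chosen by repeatedly (default 100×) drawing a random third of the
   candidate genes, clustering the samples for every *k* in 2..10, and
   recording the *k* with the best average silhouette; the modal winner is
   chosen. The vote is run twice — with PAM and with Ward hierarchical
   clustering on Minkowski distance (default exponent 3) — as a guard
   against algorithm-specific bias.
2. **Gene enrichment.** An iterative tally (default 100 × 100 random
   thirds) counts how often each gene belongs to the third with the best
   silhouette; the 100 most frequent winners form the enriched subset, and
   PAM on that subset gives interim class labels.
3. **Genome-wide re-selection.** Returning to the *complete* gene set,
   significance analysis of microarrays (SAM) scores every gene against the
   interim labels with the moderated statistic `d = Δmean / (s + s0)` and a
   label-permutation null; genes with an estimated false-discovery q-value
   of exactly 0 become the final feature set. A last PAM run on those genes
   fixes the subtype labels and medoids.

The medoids — actual patient expression profiles — make the model portable:
a new cohort is classified by assigning each sample to its Euclidean-nearest
medoid. Verification tools include bootstrap co-clustering stability,
the bimodality index `BI = √(π(1−π))·|μ₁−μ₂|/σ` from a common-variance
two-component Gaussian mixture (BI > 1.1 ≈ visually evident bimodality),
and PCA separability of the final solution. Downstream reporting covers
Fisher/t-test clinical comparisons, between-subtype fold changes
(`FC = 2^(mean₁ − mean₂)`), and hypergeometric over-representation of
user-supplied gene sets with Bonferroni correction.

A synthetic-cohort generator (`generate_cohort()`, `generate_cohort_pair()`)
draws two-subtype cohorts with controlled bimodal signal genes, noise genes,
missing data and subtype-linked clinical attributes, so the whole pipeline is
testable without any data download.

## Worked example

```r
library(sepsisSubtypes)

pair <- generate_cohort_pair(cohort_spec(seed = 11))   # 55 + 70 patients
m <- impute_missing(pair$derivation$expression)

res <- discover_subtypes(m, pair$derivation$sepsis_gene_list,
                         n_reps = 50, n_outer = 25, n_inner = 25,
                         top_m = 50, n_permutations = 200, seed = 5)
print(res)
#> Subtype discovery: k = 2
#>     stage n_genes cluster_sizes avg_silhouette
#>   initial      66         33/22      0.4348252
#>  enriched      50         33/22      0.4897434
#>     final      37         33/22      0.5674497

cls <- classify_by_medoid(res$model, impute_missing(pair$validation$expression))
print(cls)
#> Cluster solution: k = 2, sizes = 42/28, avg silhouette = 0.547
adjusted_rand_index(cls$labels, pair$validation$truth_labels)
#> [1] 1

print(compare_clinical(pair$validation$clinical, cls$labels), digits = 3)
#>       attribute       type subtype1 subtype2  p_value note
#> 1 severe_sepsis     binary     7.14     42.9 0.000668
#> 2  septic_shock     binary    76.19     50.0 0.038867
#> 3           age continuous    64.00     61.1 0.389967
#> 4      los_days continuous    29.96     39.4 0.098311
#> 5     apache_ii continuous    21.10     19.0 0.143982
```

Read: silhouette cohesion rises through the three enrichment stages
(0.43 → 0.49 → 0.57); both backends vote k = 2; the 37-gene final feature
set recovers the planted subtypes exactly in both cohorts (ARI = 1; subtype
numbering is arbitrary, so the severe-sepsis-rich planted group appears here
as "subtype 2" at 42.9% vs 7.1%, and the binary rows are percentages).
Verification on the final feature space:

```r
pc <- pca_separation(m[res$model$signature_genes, ])
#> PC1 variance fraction 0.69, PC1 bimodality index 9.74
```

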