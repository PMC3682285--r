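#' Discover molecular subtypes in a derivation cohort
#'
#' The multi-stage feature-selection and clustering pipeline:
#'
#' * **Stage A** — restrict the matrix to the curated sepsis-related gene
#'   list; choose the number of clusters `k` by resampled silhouette voting
#'   with both the PAM and hierarchical backends ([select_k()]; on
#'   disagreement the PAM choice wins with a warning); PAM at `k` gives the
#'   initial solution.
#' * **Stage B** — run the iterative gene-enrichment tally
#'   ([enrich_genes()]) and re-cluster on the enriched subset.
#' * **Stage C** — return to the complete gene set and run SAM
#'   ([sam_two_class()]) against the enriched labels; the q = 0 genes form
#'   the final feature set, on which a last PAM clustering yields the final
#'   labels and the medoids that define the transferable subtype model.
#'
#' @param m Imputed genes x samples matrix (the complete platform).
#' @param sepsis_genes Curated candidate gene IDs (must intersect the
#'   platform).
#' @param k_range,n_reps,subset_fraction Passed to [select_k()].
#' @param n_outer,n_inner,top_m Passed to [enrich_genes()].
#' @param n_permutations Passed to [sam_two_class()].
#' @param minkowski_p Exponent of the hierarchical backend's metric.
#' @param seed Integer seed; stage seeds are derived from it.
#' @return List of class `"subtype_discovery"`: `model` (a
#'   `"subtype_model"`: `signature_genes`, `medoids` matrix, `k`,
#'   `provenance`), the three stage `"cluster_solution"`s (`initial`,
#'   `enriched`, `final`), `k_selection` (both backends), `tally`, `sam`,
#'   and a `provenance` data.frame of per-stage gene counts, cluster sizes
#'   and average silhouettes.
#' @export
discover_subtypes <- function(m, sepsis_genes, k_range = 2:10, n_reps = 100,
                              subset_fraction = 1 / 3, n_outer = 100,
                              n_inner = 100, top_m = 100,
                              n_permutations = 200, minkowski_p = 3,
                              seed = 1) {
  check_expression_matrix(m, require_complete = TRUE)

  # Stage A: candidate restriction and cluster-number selection
  ms <- restrict_to_gene_list(m, sepsis_genes)
  ks_pam <- select_k(ms, k_range = k_range, n_reps = n_reps,
                     subset_fraction = subset_fraction, algorithm = "pam",
                     seed = seed + 1L)
  ks_hier <- select_k(ms, k_range = k_range, n_reps = n_reps,
                      subset_fraction = subset_fraction,
                      algorithm = "hierarchical", minkowski_p = minkowski_p,
                      seed = seed + 2L)
  if (ks_pam$chosen_k != ks_hier$chosen_k)
    warning(sprintf(
      "cluster-number backends disagree (PAM k = %d, hierarchical k = %d); using PAM's",
      ks_pam$chosen_k, ks_hier$chosen_k))
  k <- ks_pam$chosen_k
  initial <- pam_cluster(distance_matrix(ms, "euclidean"), k)

  # Stage B: enrichment tally on the candidate genes
  tally <- enrich_genes(ms, k, n_outer = n_outer, n_inner = n_inner,
                        subset_fraction = subset_fraction, top_m = top_m,
                        seed = seed + 3L)
  me <- ms[tally$enriched_subset, , drop = FALSE]
  enriched <- pam_cluster(distance_matrix(me, "euclidean"), k)

  # Stage C: SAM over the complete gene set with the enriched labels
  sam <- sam_two_class(m, enriched$labels, n_permutations = n_permutations,
                       seed = seed + 4L)
  final_genes <- select_q_zero(sam)
  if (!length(final_genes))
    stop("no genes reached q = 0; the cohort shows no reliable subtype ",
         "signal at this sample size / effect size")
  mf <- m[final_genes, , drop = FALSE]
  final <- pam_cluster(distance_matrix(mf, "euclidean"), k)
  medoids <- mf[, final$medoid_indices, drop = FALSE]
  colnames(medoids) <- paste0("subtype", seq_len(k))

  provenance <- data.frame(
    stage = c("initial", "enriched", "final"),
    n_genes = c(nrow(ms), nrow(me), nrow(mf)),
    cluster_sizes = vapply(list(initial, enriched, final), function(s)
      paste(tabulate(s$labels, s$k), collapse = "/"), character(1)),
    avg_silhouette = c(initial$avg_silhouette, enriched$avg_silhouette,
                       final$avg_silhouette),
    stringsAsFactors = FALSE)

  if (is.finite(final$avg_silhouette) && final$avg_silhouette < 0.15)
    warning(sprintf(
      "weak final structure: average silhouette %.3f < 0.15; the subtypes may not be distinct",
      final$avg_silhouette))

  model <- structure(list(signature_genes = final_genes, medoids = medoids,
                          k = k, provenance = provenance),
                     class = "subtype_model")
  structure(list(model = model, initial = initial, enriched = enriched,
                 final = final,
                 k_selection = list(pam = ks_pam, hierarchical = ks_hier),
                 tally = tally, sam = sam, provenance = provenance,
                 seed = seed),
            class = "subtype_discovery")
}

#' @export
print.subtype_discovery <- function(x, ...) {
  cat(sprintf("Subtype discovery: k = %d\n", x$model$k))
  print(x$provenance, row.names = FALSE)
  invisible(x)
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf("Subtype model: k = %d, %d signature genes\n",
              x$k, length(x$signature_genes)))
  invisible(x)
}

#' Agreement between two partitions
#'
#' Counts matching assignments after the best one-to-one relabelling of
#' clusters (label names carry no meaning in unsupervised results) and
#' computes the adjusted Rand index, a chance-corrected agreement measure
#' that is invariant to label permutation.
#'
#' @param a,b Equal-length label vectors.
#' @return List: `agreement` (matched samples under the best relabelling),
#'   `n`, and `ari`.
#' @export
compare_partitions <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  ka <- nrow(tab); kb <- ncol(tab)
  if (max(ka, kb) > 8L) {
    # greedy matching for many clusters; exact enumeration below for few
    agreement <- sum(apply(tab, 1L, max))
  } else {
    small <- if (ka <= kb) tab else t(tab)
    idx_perms <- permutations_of(seq_len(ncol(small)))
    agreement <- max(vapply(idx_perms, function(p) {
      sum(small[cbind(seq_len(nrow(small)), p[seq_len(nrow(small))])])
    }, numeric(1)))
  }
  list(agreement = as.integer(agreement), n = length(a),
       ari = adjusted_rand_index(a, b))
}

#' Adjusted Rand index
#'
#' @param a,b Equal-length label vectors.
#' @return ARI in [-1, 1]; 1 for identical partitions up to relabelling.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial and identical in form
  (sij - expected) / denom
}

# All permutations of a small vector (used for exact cluster matching).
permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permutations_of(v[-i]), function(p) c(v[i], p)))
  out
}
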