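#' Select the number of clusters by resampled silhouette voting
#'
#' Repeatedly draws a random third of the genes, clusters the samples on
#' that subset for every `k` in `k_range`, and records the `k` with the
#' highest average silhouette width; the chosen `k` is the modal winner
#' across repetitions. Run with the PAM backend (Euclidean distance) or the
#' hierarchical backend (Ward agglomeration on Minkowski distance) — using
#' both and checking agreement guards against algorithm-specific bias.
#' Ties (equal silhouettes within a repetition, or equal votes) go to the
#' smaller `k`.
#'
#' @param m Imputed genes x samples matrix (at least 3 genes).
#' @param k_range Candidate cluster numbers (default 2..10).
#' @param n_reps Number of random-subset repetitions (default 100).
#' @param subset_fraction Fraction of genes drawn per repetition without
#'   replacement (default 1/3; `floor(G * subset_fraction)` genes).
#' @param algorithm `"pam"` or `"hierarchical"`.
#' @param minkowski_p Minkowski exponent for the hierarchical backend.
#' @param seed Integer RNG seed.
#' @return List of class `"k_selection"`: `chosen_k`, `votes` (named count
#'   per k), `records` (per-repetition best k, best silhouette and gene
#'   subset) and the `algorithm` tag.
#' @export
select_k <- function(m, k_range = 2:10, n_reps = 100, subset_fraction = 1 / 3,
                     algorithm = c("pam", "hierarchical"), minkowski_p = 3,
                     seed = 1) {
  algorithm <- match.arg(algorithm)
  check_expression_matrix(m, require_complete = TRUE)
  g <- nrow(m)
  n <- ncol(m)
  if (g < 3L) stop("need at least 3 genes to draw random thirds")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > n - 1L)
    stop("`k_range` must lie within [2, n_samples - 1]")
  n_sub <- max(2L, floor(g * subset_fraction))
  set.seed(seed)
  records <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(g, n_sub)
    d <- if (algorithm == "pam")
      distance_matrix(m[idx, , drop = FALSE], "euclidean")
    else
      distance_matrix(m[idx, , drop = FALSE], "minkowski", p = minkowski_p)
    sils <- vapply(k_range, function(k) {
      sol <- if (algorithm == "pam") pam_cluster(d, k) else hier_cluster(d, k)
      sol$avg_silhouette
    }, numeric(1))
    best <- which.max(sils)  # first maximum = smallest k on ties
    records[[r]] <- list(genes = rownames(m)[idx], best_k = k_range[best],
                         best_silhouette = sils[best])
  }
  wins <- vapply(records, function(r) r$best_k, integer(1))
  votes <- vapply(k_range, function(k) sum(wins == k), integer(1))
  names(votes) <- k_range
  chosen <- k_range[which.max(votes)]  # ties -> smaller k
  structure(list(chosen_k = chosen, votes = votes, records = records,
                 algorithm = algorithm, n_reps = n_reps, seed = seed),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("k selection (%s backend, %d repetitions): chosen k = %d\n",
              x$algorithm, x$n_reps, x$chosen_k))
  print(x$votes)
  invisible(x)
}

#' Iterative gene-enrichment tally
#'
#' The discovery step that concentrates the candidate list onto the most
#' discriminatory genes: in each of `n_outer` repetitions, `n_inner` random
#' thirds of the genes are drawn and PAM-clustered at `k`; the third with the
#' highest average silhouette width is the repetition's winner and each of
#' its member genes gains one tally count. The `top_m` most frequently
#' winning genes form the enriched subset.
#'
#' @param m Imputed genes x samples matrix.
#' @param k Number of clusters (from [select_k()]).
#' @param n_outer Number of tally repetitions (default 100).
#' @param n_inner Candidate random thirds per repetition (default 100).
#' @param subset_fraction Fraction of genes per draw (default 1/3).
#' @param top_m Size of the enriched subset (default 100; capped at the
#'   number of genes with a positive count, with a warning if `top_m`
#'   exceeds the gene count).
#' @param seed Integer RNG seed.
#' @return List of class `"enrichment_tally"`: `counts` (named inclusion
#'   count per gene, total `n_outer * floor(G/3)`) and `enriched_subset`
#'   (gene IDs sorted by count descending, ties broken lexicographically).
#' @export
enrich_genes <- function(m, k, n_outer = 100, n_inner = 100,
                         subset_fraction = 1 / 3, top_m = 100, seed = 1) {
  check_expression_matrix(m, require_complete = TRUE)
  g <- nrow(m)
  if (g < 3L) stop("need at least 3 genes to draw random thirds")
  if (top_m > g) {
    warning("`top_m` exceeds the number of genes; capping at ", g)
    top_m <- g
  }
  n_sub <- max(2L, floor(g * subset_fraction))
  set.seed(seed)
  counts <- stats::setNames(integer(g), rownames(m))
  for (o in seq_len(n_outer)) {
    best_sil <- -Inf
    best_idx <- NULL
    for (i in seq_len(n_inner)) {
      idx <- sample.int(g, n_sub)
      d <- distance_matrix(m[idx, , drop = FALSE], "euclidean")
      sil <- pam_cluster(d, k)$avg_silhouette
      if (sil > best_sil) { best_sil <- sil; best_idx <- idx }
    }
    counts[best_idx] <- counts[best_idx] + 1L
  }
  pos <- names(counts)[counts > 0L]
  ord <- pos[order(-counts[pos], pos)]
  structure(list(counts = counts,
                 enriched_subset = utils::head(ord, top_m),
                 n_outer = n_outer, n_inner = n_inner, top_m = top_m,
                 seed = seed),
            class = "enrichment_tally")
}

#' @export
print.enrichment_tally <- function(x, ...) {
  cat(sprintf("Gene-enrichment tally: %d x %d repetitions, %d genes in enriched subset\n",
              x$n_outer, x$n_inner, length(x$enriched_subset)))
  invisible(x)
}
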