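#' Extract the differentially co-expressed gene module
#'
#' Clusters genes hierarchically on unsigned correlation distance
#' (`1 - |r|`, Ward agglomeration), cuts the tree into every module count in
#' `n_modules_range`, and scores each module by the mean absolute
#' standardised between-subtype difference of its member genes
#' (`|mean1 - mean2| / pooled within-subtype SD`). The single
#' maximal-contrast module across all cuts is returned, provided its mean
#' contrast exceeds `min_contrast`; correlated genes therefore travel
#' together, which is what makes the resulting list a co-expression
#' signature rather than a ranked gene list.
#'
#' @param m Imputed genes x samples matrix.
#' @param labels Two-subtype labels over samples.
#' @param n_modules_range Module counts to try when cutting the gene tree
#'   (default 2..10).
#' @param min_contrast Contrast floor in within-subtype SD units
#'   (default 1.0); if no module passes, an empty list is returned with a
#'   warning.
#' @return Character vector of module gene IDs (possibly empty); attributes
#'   `"contrast"` (the winning module's mean contrast) and `"gene_table"`
#'   (per-gene module membership and contrast for the winning cut).
#' @export
extract_coexpressed <- function(m, labels, n_modules_range = 2:10,
                                min_contrast = 1.0) {
  check_expression_matrix(m, require_complete = TRUE)
  labels <- as.vector(labels)
  if (length(labels) != ncol(m)) stop("`labels` length must match samples")
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("co-expression contrast needs exactly 2 subtypes")
  i1 <- labels == lev[1L]; i2 <- labels == lev[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("each subtype needs at least 2 samples")

  m1 <- rowMeans(m[, i1, drop = FALSE]); m2 <- rowMeans(m[, i2, drop = FALSE])
  v1 <- apply(m[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(m[, i2, drop = FALSE], 1L, stats::var)
  pooled_sd <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  floor_sd <- pmax(pooled_sd, 1e-8 * max(pooled_sd, 1e-8))
  contrast <- abs(m1 - m2) / floor_sd

  cc <- suppressWarnings(stats::cor(t(m)))
  cc[!is.finite(cc)] <- 0  # constant genes correlate with nothing
  # unsigned: genes moving in opposite directions along the same subtype
  # axis belong to the same module
  d <- stats::as.dist(1 - abs(cc))
  tree <- stats::hclust(d, method = "ward.D2")

  n_modules_range <- n_modules_range[n_modules_range >= 2 &
                                       n_modules_range < nrow(m)]
  best <- list(score = -Inf, genes = character(0), cut = NA_integer_,
               membership = NULL)
  for (nm in n_modules_range) {
    mem <- stats::cutree(tree, k = nm)
    for (mod in unique(mem)) {
      genes <- rownames(m)[mem == mod]
      score <- mean(contrast[genes])
      if (score > best$score)
        best <- list(score = score, genes = genes, cut = nm, membership = mem)
    }
  }
  if (!is.finite(best$score) || best$score <= min_contrast) {
    warning(sprintf(
      "no co-expression module exceeds the contrast floor (best %.3f <= %.3f)",
      max(best$score, 0), min_contrast))
    out <- character(0)
  } else out <- best$genes
  attr(out, "contrast") <- best$score
  attr(out, "gene_table") <- data.frame(
    gene_id = rownames(m),
    module = if (is.null(best$membership)) NA_integer_ else best$membership,
    contrast = unname(contrast),
    in_signature = rownames(m) %in% out,
    stringsAsFactors = FALSE)
  out
}

#' Intersect per-cohort co-expression signatures
#'
#' Order-stable intersection (first argument's order), the rule by which a
#' derivation-cohort and validation-cohort gene list are merged into the
#' final cross-cohort gene signature.
#'
#' @param a,b Character vectors of gene IDs (derivation first).
#' @return Character vector `a` restricted to members of `b`.
#' @export
intersect_signatures <- function(a, b) {
  a <- as.character(a)
  a[a %in% as.character(b)]
}

#' Classify samples by nearest derivation medoid
#'
#' Transfers a discovered subtype model to a new cohort: each sample is
#' restricted to the model's signature genes and assigned the subtype of the
#' Euclidean-nearest medoid (ties, a probability-zero event on continuous
#' data, go to subtype 1). Silhouette widths are computed on the new
#' cohort's own distance matrix under the assigned labels, so the reported
#' average measures how well the transferred structure fits the new data.
#'
#' @param model A `"subtype_model"` from [discover_subtypes()].
#' @param m Imputed genes x samples matrix containing every signature gene.
#' @return A `"cluster_solution"` over the new cohort's samples, with a
#'   `"medoid_distances"` attribute (samples x k matrix). If all samples
#'   fall in one subtype the silhouettes are undefined and `avg_silhouette`
#'   is `NA`.
#' @export
classify_by_medoid <- function(model, m) {
  if (!inherits(model, "subtype_model")) stop("`model` must be a subtype_model")
  check_expression_matrix(m, require_complete = TRUE)
  missing <- setdiff(model$signature_genes, rownames(m))
  if (length(missing))
    stop("cohort lacks signature genes: ", paste(missing, collapse = ", "))
  x <- m[model$signature_genes, , drop = FALSE]
  dists <- vapply(seq_len(model$k), function(j)
    sqrt(colSums((x - model$medoids[, j])^2)), numeric(ncol(x)))
  dists <- matrix(dists, ncol = model$k,
                  dimnames = list(colnames(m), colnames(model$medoids)))
  labels <- apply(dists, 1L, which.min)  # which.min: ties -> subtype 1
  d <- distance_matrix(x, "euclidean")
  if (length(unique(labels)) >= 2L) {
    sil <- silhouette_widths(d, labels)
  } else {
    warning("all samples assigned to one subtype; silhouettes undefined")
    sil <- list(widths = rep(NA_real_, ncol(x)), average = NA_real_)
  }
  sol <- structure(list(labels = as.integer(labels), k = model$k,
                        medoid_indices = integer(0),
                        silhouettes = sil$widths,
                        avg_silhouette = sil$average),
                   class = "cluster_solution")
  attr(sol, "medoid_distances") <- dists
  sol
}
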