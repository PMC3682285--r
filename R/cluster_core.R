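#' Pairwise sample distances
#'
#' Minkowski distance between samples (columns), with genes as coordinates:
#' `d(i,j) = (sum_g |x_gi - x_gj|^p)^(1/p)`. `metric = "euclidean"` is the
#' `p = 2` special case and is the metric of the main PAM clustering;
#' `"minkowski"` (default exponent `p = 3`, a genuinely different geometry)
#' is used by the hierarchical cross-check.
#'
#' @param m Genes x samples matrix without missing values.
#' @param metric `"euclidean"` or `"minkowski"`.
#' @param p Minkowski exponent (ignored for `"euclidean"`).
#' @return A `stats::dist` object over samples, with a `"metric"` attribute.
#' @export
distance_matrix <- function(m, metric = c("euclidean", "minkowski"), p = 3) {
  metric <- match.arg(metric)
  check_expression_matrix(m, require_complete = TRUE)
  d <- if (metric == "euclidean") {
    stats::dist(t(m), method = "euclidean")
  } else {
    stopifnot(is.numeric(p), length(p) == 1L, p >= 1)
    stats::dist(t(m), method = "minkowski", p = p)
  }
  attr(d, "metric") <- if (metric == "euclidean") "euclidean" else sprintf("minkowski(p=%g)", p)
  d
}

# Shared constructor for clustering results.
cluster_solution <- function(labels, k, d, medoid_indices = integer(0)) {
  sil <- if (k >= 2L) silhouette_widths(d, labels) else
    list(widths = rep(0, length(labels)), average = NA_real_)
  structure(list(labels = labels, k = as.integer(k),
                 medoid_indices = medoid_indices,
                 silhouettes = sil$widths, avg_silhouette = sil$average),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Cluster solution: k = %d, sizes = %s, avg silhouette = %s\n",
              x$k, paste(tabulate(x$labels, x$k), collapse = "/"),
              format(x$avg_silhouette, digits = 3)))
  invisible(x)
}

#' Partitioning around medoids
#'
#' Classic BUILD + SWAP k-medoids (via [cluster::pam()]): BUILD greedily
#' seeds `k` medoids minimising total distance to the nearest medoid, SWAP
#' exchanges medoid/non-medoid pairs while the total cost strictly
#' decreases. Labels are nearest-medoid assignments; per-sample silhouette
#' widths are attached.
#'
#' @param d `stats::dist` object (see [distance_matrix()]).
#' @param k Number of clusters, `2 <= k < n`.
#' @return A `"cluster_solution"`: integer `labels` (1..k), `medoid_indices`
#'   (positions in the sample order), per-sample `silhouettes`,
#'   `avg_silhouette` and `k`. The total cost (sum of distances to assigned
#'   medoids) is in the `"cost"` attribute.
#' @export
pam_cluster <- function(d, k) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (k < 2L || k >= n) stop("`k` must satisfy 2 <= k < n")
  fit <- cluster::pam(d, k = k, diss = TRUE, cluster.only = FALSE,
                      keep.diss = FALSE, keep.data = FALSE)
  medoids <- as.integer(fit$id.med)
  labels <- as.integer(fit$clustering)
  sol <- cluster_solution(labels, k, d, medoid_indices = medoids)
  dm <- as.matrix(d)
  attr(sol, "cost") <- sum(dm[cbind(seq_len(n), medoids[labels])])
  sol
}

#' Agglomerative hierarchical clustering cut to k clusters
#'
#' Ward's minimum-variance agglomeration (Lance-Williams `ward.D2` update)
#' on an arbitrary distance, tree cut to exactly `k` clusters. Labels are
#' renumbered 1..k by first appearance in sample order; no medoids are
#' defined.
#'
#' @param d `stats::dist` object.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param linkage Agglomeration method; only `"ward"` is supported.
#' @return A `"cluster_solution"` (with empty `medoid_indices`); the
#'   `hclust` tree is in the `"tree"` attribute. For `k = 1` silhouettes are
#'   undefined and `avg_silhouette` is `NA`.
#' @export
hier_cluster <- function(d, k, linkage = c("ward")) {
  match.arg(linkage)
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (k < 1L || k > n) stop("`k` must satisfy 1 <= k <= n")
  tree <- stats::hclust(d, method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  labels <- as.integer(match(raw, unique(raw)))  # relabel by first appearance
  sol <- cluster_solution(labels, k, d)
  attr(sol, "tree") <- tree
  sol
}

#' Silhouette widths of a partition
#'
#' For sample i with within-cluster mean distance `a(i)` (self excluded) and
#' `b(i)` the smallest mean distance to another cluster,
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`. Singleton clusters get
#' `s(i) = 0`, as does the degenerate `a = b = 0` case (coincident points).
#' High average widths indicate tight, well-separated clusters.
#'
#' @param d `stats::dist` object.
#' @param labels Integer cluster labels (>= 2 non-empty clusters).
#' @return List with per-sample `widths` (in [-1, 1]) and their `average`.
#' @export
silhouette_widths <- function(d, labels) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  labels <- as.integer(labels)
  if (length(labels) != n) stop("`labels` length must match the distance matrix")
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("silhouettes need at least 2 clusters")
  dm <- as.matrix(d)
  sizes <- table(factor(labels, levels = ks))
  # mean distance of every sample to every cluster
  cl_sum <- vapply(ks, function(cl) rowSums(dm[, labels == cl, drop = FALSE]),
                   numeric(n))
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- match(labels[i], ks)
    n_own <- sizes[[own]]
    if (n_own == 1L) { widths[i] <- 0; next }
    a <- cl_sum[i, own] / (n_own - 1L)
    b <- min(cl_sum[i, -own] / as.numeric(sizes[-own]))
    widths[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(widths = widths, average = mean(widths))
}
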