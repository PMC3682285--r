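#' Bootstrap co-clustering stability
#'
#' Resamples the cohort with replacement `n_resamples` times, clusters the
#' unique drawn samples hierarchically (Euclidean distance, Ward
#' agglomeration) cut at `k`, and records for every co-drawn pair of samples
#' whether they land in the same branch. The resulting proportion matrix
#' reads like a stability heat map: values near 1 mean two samples cluster
#' together essentially always, values near 0 essentially never.
#'
#' @param m Imputed genes x samples matrix.
#' @param k Number of clusters.
#' @param n_resamples Number of bootstrap resamples (default 200).
#' @param seed Integer RNG seed.
#' @return List of class `"bootstrap_map"`: `proportion` (n x n, `NA` for
#'   pairs never co-drawn), `co_cluster` and `co_drawn` count matrices,
#'   `n_resamples` and the number of `skipped` resamples (fewer unique
#'   samples than `k`).
#' @export
bootstrap_stability <- function(m, k, n_resamples = 200, seed = 1) {
  check_expression_matrix(m, require_complete = TRUE)
  n <- ncol(m)
  if (k < 2L || k >= n) stop("`k` must satisfy 2 <= k < n")
  set.seed(seed)
  together <- matrix(0L, n, n, dimnames = list(colnames(m), colnames(m)))
  drawn <- together
  skipped <- 0L
  for (b in seq_len(n_resamples)) {
    u <- sort(unique(sample.int(n, n, replace = TRUE)))
    if (length(u) <= k) { skipped <- skipped + 1L; next }
    d <- distance_matrix(m[, u, drop = FALSE], "euclidean")
    labels <- hier_cluster(d, k)$labels
    drawn[u, u] <- drawn[u, u] + 1L
    same <- outer(labels, labels, `==`)
    together[u, u] <- together[u, u] + same
  }
  prop <- ifelse(drawn > 0L, together / pmax(drawn, 1L), NA_real_)
  structure(list(proportion = prop, co_cluster = together, co_drawn = drawn,
                 n_resamples = n_resamples, skipped = skipped, seed = seed),
            class = "bootstrap_map")
}

#' Bimodality index of a distribution
#'
#' Fits a two-component, common-variance Gaussian mixture by EM and returns
#' the bimodality index `BI = sqrt(pi * (1 - pi)) * |mu1 - mu2| / sigma`,
#' a measure of how far apart and how balanced the two modes are. Values
#' above about 1.1 correspond to distributions whose two modes are evident
#' by eye in a density plot, which is the working threshold used when
#' screening genes for subtype-driven bimodality. The index is invariant to
#' affine rescaling of the data.
#'
#' EM uses multiple starts (a quantile-based split plus random pairs of
#' observations as initial means; 10 starts, up to 500 iterations,
#' log-likelihood tolerance 1e-8) and keeps the best-likelihood fit.
#'
#' @param x Numeric vector (at least 10 finite values).
#' @param seed Integer RNG seed for the random starts.
#' @param n_starts,max_iter,tol EM control parameters.
#' @return List of class `"bimodality_fit"`: `pi`, `mu1`, `mu2`, `sigma`,
#'   `delta` (`|mu1 - mu2| / sigma`), `BI`, `loglik`, `loglik_trace` (of the
#'   winning start) and `converged`. Zero-variance input gives `BI = 0` with
#'   `converged = FALSE`.
#' @export
bimodality_index <- function(x, seed = 1, n_starts = 10, max_iter = 500,
                             tol = 1e-8) {
  x <- x[is.finite(x)]
  if (length(x) < 10L) stop("bimodality_index needs at least 10 finite values")
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    return(structure(list(pi = 0.5, mu1 = mean(x), mu2 = mean(x), sigma = 0,
                          delta = 0, BI = 0, loglik = NA_real_,
                          loglik_trace = numeric(0), converged = FALSE),
                     class = "bimodality_fit"))
  }
  set.seed(seed)
  # fit on standardised data: the index is affine-invariant, and this makes
  # the EM (including its stopping rule) exactly so
  ctr <- mean(x); scl <- stats::sd(x)
  z <- (x - ctr) / scl
  starts <- c(list(c(stats::quantile(z, 0.25, names = FALSE),
                     stats::quantile(z, 0.75, names = FALSE))),
              lapply(seq_len(max(0L, n_starts - 1L)),
                     function(i) sample(z, 2L)))
  best <- NULL
  for (st in starts) {
    if (abs(st[1] - st[2]) < 1e-12) next
    fit <- em_mix2_common(z, mu = sort(st), max_iter = max_iter, tol = tol)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(pi = 0.5, mu1 = mean(x), mu2 = mean(x),
                          sigma = stats::sd(x), delta = 0, BI = 0,
                          loglik = NA_real_, loglik_trace = numeric(0),
                          converged = FALSE),
                     class = "bimodality_fit"))
  }
  delta <- abs(best$mu[2] - best$mu[1]) / best$sigma
  # report parameters on the original scale; loglik too (constant Jacobian)
  structure(list(pi = best$pi, mu1 = ctr + scl * best$mu[1],
                 mu2 = ctr + scl * best$mu[2], sigma = scl * best$sigma,
                 delta = delta,
                 BI = sqrt(best$pi * (1 - best$pi)) * delta,
                 loglik = best$loglik - length(x) * log(scl),
                 loglik_trace = best$trace - length(x) * log(scl),
                 converged = best$converged),
            class = "bimodality_fit")
}

# EM for a two-component univariate Gaussian mixture with a common variance.
# Returns NULL if the fit degenerates (vanishing component or variance).
em_mix2_common <- function(x, mu, max_iter, tol) {
  n <- length(x)
  pi1 <- 0.5
  sigma <- stats::sd(x) / 2
  if (sigma <= 0) return(NULL)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f1 <- pi1 * stats::dnorm(x, mu[1], sigma)
    f2 <- (1 - pi1) * stats::dnorm(x, mu[2], sigma)
    tot <- f1 + f2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    # absolute tolerance: EM can plateau near a symmetric saddle with tiny
    # per-iteration gains long before reaching the maximiser
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    g1 <- f1 / tot
    w1 <- sum(g1); w2 <- n - w1
    if (w1 < 1e-8 || w2 < 1e-8) return(NULL)
    pi1 <- w1 / n
    mu <- c(sum(g1 * x) / w1, sum((1 - g1) * x) / w2)
    sigma <- sqrt((sum(g1 * (x - mu[1])^2) + sum((1 - g1) * (x - mu[2])^2)) / n)
    if (!is.finite(sigma) || sigma < 1e-10 * stats::sd(x)) return(NULL)
  }
  if (mu[1] > mu[2]) { mu <- rev(mu); pi1 <- 1 - pi1 } # orient low mode first
  list(pi = pi1, mu = mu, sigma = sigma, loglik = trace[length(trace)],
       trace = trace, converged = converged)
}

#' Fraction of genes with a bimodal expression distribution
#'
#' Computes the bimodality index of each listed gene across samples and
#' reports the fraction exceeding `threshold` (default 1.1, the visual
#' bimodality level). Distinct subtypes should leave a sizeable fraction of
#' their differential genes bimodal.
#'
#' @param m Imputed genes x samples matrix.
#' @param genes Gene IDs to screen (default: all genes).
#' @param threshold Bimodality-index cutoff (default 1.1).
#' @param seed Integer RNG seed passed to the per-gene EM starts.
#' @return List: `fraction`, `threshold` and a per-gene data.frame `table`
#'   with `gene_id`, `BI` and `bimodal`.
#' @export
bimodal_gene_fraction <- function(m, genes = rownames(m), threshold = 1.1,
                                  seed = 1) {
  check_expression_matrix(m, require_complete = TRUE)
  genes <- as.character(genes)
  if (!length(genes)) stop("`genes` must list at least one gene")
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stop("genes absent from the matrix: ", paste(missing, collapse = ", "))
  bi <- vapply(genes, function(gid) bimodality_index(m[gid, ], seed = seed)$BI,
               numeric(1))
  tab <- data.frame(gene_id = genes, BI = unname(bi),
                    bimodal = unname(bi > threshold),
                    stringsAsFactors = FALSE)
  list(fraction = mean(tab$bimodal), threshold = threshold, table = tab)
}

#' Principal-component separability of a clustering
#'
#' PCA with samples as observations and genes as (centred, unscaled)
#' variables; reports the fraction of variance on the first principal
#' component, the PC1 scores, and the bimodality index of those scores. Two
#' genuinely distinct subtypes should be separable along PC1 and leave its
#' score distribution bimodal.
#'
#' @param m Imputed genes x samples matrix (at least 3 samples).
#' @param labels Optional cluster labels, echoed alongside the scores for
#'   downstream plotting; they do not affect the decomposition.
#' @param seed Integer RNG seed for the bimodality EM starts.
#' @return List: `pc1_variance_fraction`, `pc1_scores` (named by sample),
#'   `bimodality` (a `"bimodality_fit"` of the scores) and `labels`.
#' @export
pca_separation <- function(m, labels = NULL, seed = 1) {
  check_expression_matrix(m, require_complete = TRUE)
  if (ncol(m) < 3L) stop("PCA needs at least 3 samples")
  pr <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  varfrac <- pr$sdev[1L]^2 / sum(pr$sdev^2)
  scores <- stats::setNames(pr$x[, 1L], colnames(m))
  list(pc1_variance_fraction = varfrac, pc1_scores = scores,
       bimodality = bimodality_index(scores, seed = seed), labels = labels)
}
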