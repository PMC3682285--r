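#' Two-class unpaired significance analysis of microarrays (SAM)
#'
#' Scores each gene with the moderated relative difference
#' `d = (mean2 - mean1) / (s + s0)`, where `s` is the pooled standard error
#' `sqrt((1/n1 + 1/n2) * (SS1 + SS2) / (n1 + n2 - 2))` and `s0` is an
#' exchangeability constant chosen to make the spread of `d` roughly
#' independent of `s` (coefficient-of-variation minimisation over the
#' percentile grid 0, 5, ..., 100 of `s`). The null distribution of `d`
#' comes from class-label permutations — all distinct assignments when their
#' number is at most `n_permutations`, otherwise a uniform random sample.
#' Per-gene q-values are the SAM false-discovery estimate at that gene's own
#' `|d|` threshold: `pi0` times the median permutation false-call count over
#' the observed call count, minimised over all less-stringent thresholds so
#' q is non-decreasing as `|d|` decreases. A q-value of exactly 0 means the
#' median permutation yields no call at that threshold.
#'
#' Sign convention: class labels are coded so that positive `d` means higher
#' expression in class 2.
#'
#' @param m Imputed genes x samples matrix.
#' @param labels Two-class labels over samples (each class >= 2 samples);
#'   class order follows `sort(unique(labels))`.
#' @param n_permutations Maximum number of label permutations (default 200).
#' @param s0 Optional fixed exchangeability constant; `NULL` (default) uses
#'   the coefficient-of-variation search. `s0 = 0` gives the ordinary
#'   unmoderated statistic.
#' @param pi0 `"estimate"` (default; `min(1, 2 * mean(|d| <= median null |d|))`)
#'   or `"one"` to force `pi0 = 1`.
#' @param seed Integer RNG seed for the permutation draw.
#' @return List of class `"sam_result"` with per-gene `d`, `s`, `q_value`,
#'   `selected` (`q_value == 0`), and global `s0`, `pi0`, `n_permutations`,
#'   `exhaustive` flag and `seed`.
#' @export
sam_two_class <- function(m, labels, n_permutations = 200, s0 = NULL,
                          pi0 = c("estimate", "one"), seed = 1) {
  pi0 <- match.arg(pi0)
  check_expression_matrix(m, require_complete = TRUE)
  labels <- as.vector(labels)
  if (length(labels) != ncol(m)) stop("`labels` length must match samples")
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("SAM needs exactly two classes")
  cls <- as.integer(labels == lev[2L]) + 1L  # 1 / 2
  n1 <- sum(cls == 1L); n2 <- sum(cls == 2L)
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 samples")
  n <- n1 + n2
  g <- nrow(m)

  d_stat <- function(cl1) {
    x1 <- m[, cl1, drop = FALSE]
    x2 <- m[, !cl1, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
    s <- sqrt((1 / n1 + 1 / n2) * ss / (n - 2L))
    list(r = m2 - m1, s = s)
  }
  obs <- d_stat(cls == 1L)

  if (is.null(s0)) {
    s0 <- tusher_s0(obs$r, obs$s)
  } else {
    stopifnot(is.numeric(s0), length(s0) == 1L, s0 >= 0)
    if (s0 == 0 && any(obs$s == 0))
      stop("s0 = 0 with zero-variance genes gives undefined statistics")
  }
  d <- obs$r / (obs$s + s0)

  # permutation null: indicator matrices of class-1 membership
  n_total <- choose(n, n1)
  set.seed(seed)
  if (n_total <= n_permutations) {
    combos <- utils::combn(n, n1)
    perms <- lapply(seq_len(ncol(combos)), function(j) {
      v <- logical(n); v[combos[, j]] <- TRUE; v
    })
    exhaustive <- TRUE
  } else {
    perms <- lapply(seq_len(n_permutations), function(j) {
      v <- logical(n); v[sample.int(n, n1)] <- TRUE; v
    })
    exhaustive <- FALSE
  }
  b <- length(perms)
  d_null <- vapply(perms, function(p) {
    st <- d_stat(p)
    st$r / (st$s + s0)
  }, numeric(g))                      # g x b

  abs_d <- abs(d)
  ord <- order(abs_d, decreasing = TRUE)
  thresholds <- abs_d[ord]
  calls <- vapply(thresholds, function(t) sum(abs_d >= t), integer(1))
  # per-permutation counts of |d*| >= t via sorted lookup
  null_sorted <- apply(abs(d_null), 2L, sort)
  eps <- 1e-9
  false_counts <- vapply(seq_len(b), function(j) {
    v <- null_sorted[, j]
    g - findInterval(thresholds * (1 - eps) - eps, v)
  }, integer(length(thresholds)))    # thresholds x b
  false_med <- apply(false_counts, 1L, stats::median)

  pi0_hat <- if (pi0 == "one") 1 else {
    q50 <- stats::median(abs(d_null))
    min(1, 2 * mean(abs_d <= q50))
  }
  fdr <- pmin(1, pi0_hat * false_med / pmax(1L, calls))
  q_sorted <- rev(cummin(rev(fdr)))  # min over less-stringent thresholds
  q <- numeric(g)
  q[ord] <- q_sorted
  # equal |d| must share a q-value
  q <- stats::ave(q, abs_d, FUN = min)

  structure(list(gene_ids = rownames(m), d = stats::setNames(d, rownames(m)),
                 s = stats::setNames(obs$s, rownames(m)),
                 q_value = stats::setNames(q, rownames(m)),
                 selected = stats::setNames(q == 0, rownames(m)),
                 s0 = s0, pi0 = pi0_hat, n_permutations = b,
                 exhaustive = exhaustive, seed = seed,
                 classes = lev),
            class = "sam_result")
}

# Tusher exchangeability constant: candidate s0 = percentiles 0,5,...,100 of
# s; pick the one minimising the coefficient of variation of the median
# absolute deviation of d across ~100 s-quantile windows.
tusher_s0 <- function(r, s) {
  alphas <- seq(0, 1, by = 0.05)
  cand <- stats::quantile(s, alphas, names = FALSE, type = 7)
  n_win <- min(100L, max(2L, length(s) %/% 5L))
  br <- unique(stats::quantile(s, seq(0, 1, length.out = n_win + 1L),
                               names = FALSE))
  grp <- if (length(br) > 2L)
    cut(s, br, include.lowest = TRUE) else factor(rep(1L, length(s)))
  cv <- vapply(cand, function(s0) {
    dd <- r / (s + s0)
    mads <- tapply(dd, grp, stats::mad)
    mads <- mads[is.finite(mads)]
    if (length(mads) < 2L || mean(mads) == 0) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  s0 <- cand[which.min(cv)]
  if (s0 <= 0 && any(s == 0)) s0 <- min(s[s > 0], na.rm = TRUE) * 0.01
  if (!is.finite(s0) || s0 < 0) s0 <- 0
  s0
}

#' Genes selected at q-value zero
#'
#' The final SAM selection rule: genes whose estimated false-discovery rate
#' at their own threshold is exactly zero (no false calls in the median
#' permutation), i.e. a very low likelihood of false discovery. Returned in
#' decreasing order of `|d|`; possibly empty.
#'
#' @param r A [sam_two_class()] result.
#' @return Character vector of gene IDs.
#' @export
select_q_zero <- function(r) {
  if (!inherits(r, "sam_result")) stop("`r` must be a sam_result")
  sel <- r$gene_ids[r$q_value == 0]
  sel[order(-abs(r$d[sel]))]
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf(
    "SAM two-class result: %d genes, s0 = %.4g, pi0 = %.3f, %d permutations%s\n",
    length(x$gene_ids), x$s0, x$pi0, x$n_permutations,
    if (x$exhaustive) " (exhaustive)" else ""))
  cat(sprintf("  %d genes at q = 0 (positive d = higher in class '%s')\n",
              sum(x$selected), x$classes[2L]))
  invisible(x)
}
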