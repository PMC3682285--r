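# Independent oracles and small fixture builders used across the suite.

# genes x samples matrix with canonical dimnames
expr_mat <- function(values, n_genes, n_samples) {
  matrix(values, n_genes, n_samples,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("S%02d", seq_len(n_samples))))
}

# one "gene", samples at the given 1-D coordinates
points_1d <- function(x) expr_mat(x, 1, length(x))

# exhaustive k-medoids optimum: minimum total distance to the nearest medoid
# over all medoid subsets
exhaustive_pam_cost <- function(d, k) {
  dm <- as.matrix(d)
  combos <- utils::combn(nrow(dm), k)
  min(apply(combos, 2, function(med)
    sum(apply(dm[, med, drop = FALSE], 1, min))))
}

# two-sided Fisher exact p by full enumeration of 2x2 tables with the
# observed margins (sum of probabilities of tables no more probable than
# the observed one, with the standard relative-error tie guard)
fisher_enum_p <- function(tab) {
  r <- rowSums(tab); cs <- colSums(tab)
  xs <- max(0, cs[1] - r[2]):min(r[1], cs[1])
  probs <- stats::dhyper(xs, r[1], r[2], cs[1])
  p_obs <- stats::dhyper(tab[1, 1], r[1], r[2], cs[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper-tail hypergeometric P(X >= overlap) by direct summation
hyper_enum_p <- function(overlap, set_size, universe_size, draw_size) {
  js <- overlap:min(set_size, draw_size)
  sum(choose(set_size, js) * choose(universe_size - set_size, draw_size - js)) /
    choose(universe_size, draw_size)
}

# adjusted Rand index written out long-hand from the contingency-table
# definition (independent of the package's implementation)
ari_reference <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(tab * (tab - 1) / 2)
  sum_i <- sum(rowSums(tab) * (rowSums(tab) - 1) / 2)
  sum_j <- sum(colSums(tab) * (colSums(tab) - 1) / 2)
  exp_ij <- sum_i * sum_j / (n * (n - 1) / 2)
  (sum_ij - exp_ij) / ((sum_i + sum_j) / 2 - exp_ij)
}

# three well-separated groups: block b of genes elevated in group b
three_group_matrix <- function(n_per_group = 15, genes_per_block = 20,
                               shift = 4, seed = 1) {
  set.seed(seed)
  n <- 3 * n_per_group
  g <- 3 * genes_per_block
  groups <- rep(1:3, each = n_per_group)
  m <- matrix(stats::rnorm(g * n, mean = 8), g, n)
  for (b in 1:3)
    m[(b - 1) * genes_per_block + seq_len(genes_per_block), groups == b] <-
      m[(b - 1) * genes_per_block + seq_len(genes_per_block), groups == b] + shift
  dimnames(m) <- list(sprintf("g%03d", seq_len(g)), sprintf("S%03d", seq_len(n)))
  attr(m, "groups") <- groups
  m
}
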