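test_that("bootstrap co-clustering separates tight groups cleanly", {
  co <- generate_cohort(cohort_spec(n_samples = 24, n_genes = 40,
                                    n_signal_genes = 20, delta = 5,
                                    missing_rate = 0, seed = 30))
  bs <- bootstrap_stability(co$expression, 2, n_resamples = 60, seed = 31)
  same <- outer(co$truth_labels, co$truth_labels, `==`)
  diag(same) <- NA
  within <- bs$proportion[same & !is.na(same)]
  between <- bs$proportion[!same & !is.na(same)]
  expect_gte(mean(within, na.rm = TRUE), 0.95)
  expect_lte(mean(between, na.rm = TRUE), 0.05)
  # structural invariants
  expect_true(isSymmetric(bs$proportion))
  expect_true(all(bs$proportion >= 0 & bs$proportion <= 1, na.rm = TRUE))
  expect_true(all(diag(bs$proportion)[diag(bs$co_drawn) > 0] == 1))
  # determinism
  bs2 <- bootstrap_stability(co$expression, 2, n_resamples = 60, seed = 31)
  expect_identical(bs$proportion, bs2$proportion)
})

test_that("an identical duplicated sample pair co-clusters every time", {
  set.seed(32)
  m <- expr_mat(rnorm(10 * 12), 10, 12)
  m[, 2] <- m[, 1]                      # exact duplicate pair
  m[, 7:12] <- m[, 7:12] + 6            # a separated second group
  bs <- bootstrap_stability(m, 2, n_resamples = 40, seed = 33)
  expect_equal(bs$proportion[1, 2], 1)
})

test_that("the bimodality index calibrates against its closed form", {
  set.seed(34)
  x <- c(rnorm(2500), rnorm(2500, 3))   # pi = 0.5, delta = 3 -> BI = 1.5
  fit <- bimodality_index(x, seed = 1)
  expect_true(fit$converged)
  expect_gt(fit$BI, 1.35)
  expect_lt(fit$BI, 1.65)
  # unimodal control stays below the visual-bimodality threshold
  expect_lt(bimodality_index(rnorm(5000), seed = 1)$BI, 1.1)
})

test_that("the bimodality index is affine-invariant and handles degenerate input", {
  set.seed(35)
  x <- c(rnorm(300), rnorm(200, 2.5))
  a <- bimodality_index(x, seed = 2)
  b <- bimodality_index(2 * x + 7, seed = 2)
  expect_equal(a$BI, b$BI, tolerance = 1e-6)
  z <- bimodality_index(rep(4, 50), seed = 1)
  expect_equal(z$BI, 0)
  expect_false(z$converged)
  expect_error(bimodality_index(c(1, 2, 3)), "at least 10")
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(36)
  x <- c(rnorm(400), rnorm(300, 2))
  fit <- bimodality_index(x, seed = 3)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
})

test_that("the mixture fit matches mclust's equal-variance model when available", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust resolves helpers unqualified
  set.seed(37)
  x <- c(rnorm(1500), rnorm(1000, 2.5))
  own <- bimodality_index(x, seed = 4)
  mc <- Mclust(x, G = 2, modelNames = "E", verbose = FALSE)
  mc_bi <- sqrt(prod(mc$parameters$pro)) * abs(diff(mc$parameters$mean)) /
    sqrt(mc$parameters$variance$sigmasq)
  expect_gte(own$loglik, mc$loglik - 1e-3)  # at least as good a fit
  expect_equal(own$BI, unname(mc_bi), tolerance = 0.05)
})

test_that("bimodal gene fractions separate signal from noise genes", {
  co <- generate_cohort(cohort_spec(n_samples = 200, n_genes = 60,
                                    n_signal_genes = 25, delta = 3,
                                    missing_rate = 0, seed = 38))
  sig <- bimodal_gene_fraction(co$expression, co$truth_signal_genes, seed = 1)
  expect_gte(sig$fraction, 0.9)
  noise <- setdiff(rownames(co$expression), co$truth_signal_genes)
  nul <- bimodal_gene_fraction(co$expression, noise, seed = 1)
  expect_lte(nul$fraction, 0.05)
  expect_named(sig$table, c("gene_id", "BI", "bimodal"))
  expect_error(bimodal_gene_fraction(co$expression, character(0)), "at least one")
  expect_error(bimodal_gene_fraction(co$expression, "NOPE"), "absent")
})

test_that("PCA reports a pure single-axis structure as 100% PC1 variance", {
  set.seed(39)
  scores <- rnorm(12)
  loadings <- rnorm(6)
  m <- outer(loadings, scores) + 5
  dimnames(m) <- list(sprintf("g%02d", 1:6), sprintf("S%02d", 1:12))
  pc <- pca_separation(m)
  expect_equal(pc$pc1_variance_fraction, 1.0, tolerance = 1e-10)
})

test_that("two subtypes separate along a bimodal first principal component", {
  co <- generate_cohort(cohort_spec(n_samples = 60, n_genes = 80,
                                    n_signal_genes = 30, delta = 3,
                                    missing_rate = 0, seed = 40))
  pc <- pca_separation(co$expression, labels = co$truth_labels)
  expect_gt(pc$bimodality$BI, 1.1)
  # best single PC1 threshold classifies >= 90% of samples correctly
  sc <- sort(pc$pc1_scores)
  cuts <- (sc[-1] + sc[-length(sc)]) / 2
  acc <- vapply(cuts, function(ct) {
    pred <- ifelse(pc$pc1_scores > ct, 1L, 2L)
    max(mean(pred == co$truth_labels), mean((3L - pred) == co$truth_labels))
  }, numeric(1))
  expect_gte(max(acc), 0.9)
  # labels play no role in the decomposition
  pc2 <- pca_separation(co$expression)
  expect_identical(pc$pc1_scores, pc2$pc1_scores)
})
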