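test_that("a cohort is bit-identical given the same spec and seed", {
  sp <- cohort_spec(n_samples = 20, n_genes = 50, n_signal_genes = 8,
                    missing_rate = 0.05, seed = 42)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth_labels, b$truth_labels)
  expect_identical(a$sepsis_gene_list, b$sepsis_gene_list)
  c2 <- generate_cohort(cohort_spec(n_samples = 20, n_genes = 50,
                                    n_signal_genes = 8, missing_rate = 0.05,
                                    seed = 43))
  expect_false(identical(a$expression, c2$expression))
})

test_that("delta = 0 builds a null cohort: per-gene t-tests reject at ~5%", {
  co <- generate_cohort(cohort_spec(n_samples = 80, n_genes = 400,
                                    n_signal_genes = 400, delta = 0,
                                    missing_rate = 0, seed = 2))
  p <- apply(co$expression, 1, function(v)
    stats::t.test(v[co$truth_labels == 1], v[co$truth_labels == 2])$p.value)
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.12)
})

test_that("signal genes carry the designed mixture: BI recovered at delta 2 and 3, monotone from 0 to 3", {
  est <- vapply(c(0, 1, 2, 3), function(dl) {
    co <- generate_cohort(cohort_spec(n_samples = 5000, n_genes = 2,
                                      n_signal_genes = 2, delta = dl,
                                      subtype_proportion = 0.4,
                                      missing_rate = 0, seed = 3))
    mean(vapply(rownames(co$expression), function(g)
      bimodality_index(co$expression[g, ], seed = 1)$BI, numeric(1)))
  }, numeric(1))
  pop <- sqrt(0.4 * 0.6) * c(2, 3)
  expect_lt(abs(est[3] - pop[1]) / pop[1], 0.10)
  expect_lt(abs(est[4] - pop[2]) / pop[2], 0.10)
  expect_true(all(diff(est) > 0))
})

test_that("binary clinical attributes match their per-subtype prevalences", {
  co <- generate_cohort(cohort_spec(
    n_samples = 1000, n_genes = 20, n_signal_genes = 4,
    subtype_proportion = 0.5, missing_rate = 0, seed = 5))
  sev <- co$clinical$severe_sepsis
  p1 <- mean(sev[co$truth_labels == 1])
  p2 <- mean(sev[co$truth_labels == 2])
  n1 <- sum(co$truth_labels == 1)
  n2 <- sum(co$truth_labels == 2)
  expect_lt(abs(p1 - 0.36), 1.96 * sqrt(0.36 * 0.64 / n1))
  expect_lt(abs(p2 - 0.09), 1.96 * sqrt(0.09 * 0.91 / n2))
})

test_that("write_cohort round-trips through the readers, truth included", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(n_samples = 15, n_genes = 30,
                                    n_signal_genes = 6, missing_rate = 0.1,
                                    n_high_missing_samples = 1, seed = 7))
  paths <- write_cohort(co, dir)
  back <- read_expression(paths[["expression"]])
  expect_identical(back, co$expression)        # values and missing mask
  clin <- read_clinical(paths[["clinical"]])
  expect_equal(clin$sample_id, co$clinical$sample_id)
  expect_equal(clin$severe_sepsis, co$clinical$severe_sepsis)
  expect_identical(read_gene_list(paths[["gene_list"]]), co$sepsis_gene_list)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_length(truth$labels, 15L)
  expect_setequal(unlist(truth$signal_genes), co$truth_signal_genes)
})

test_that("a forced high-missing sample survives writing and falls to the downstream filter only", {
  co <- generate_cohort(cohort_spec(n_samples = 12, n_genes = 60,
                                    n_signal_genes = 6, missing_rate = 0.02,
                                    n_high_missing_samples = 1, seed = 8))
  expect_equal(ncol(co$expression), 12L)       # present in the cohort
  filt <- filter_high_missing_samples(co$expression)
  expect_length(filt$removed, 1L)
  expect_gt(mean(is.na(co$expression[, filt$removed])), 0.80)
})

test_that("matched cohort pairs share gene-level structure but not samples", {
  pair <- generate_cohort_pair(cohort_spec(n_samples = 20, n_genes = 60,
                                           n_signal_genes = 10, seed = 9))
  expect_identical(pair$derivation$truth_signal_genes,
                   pair$validation$truth_signal_genes)
  expect_identical(pair$derivation$sepsis_gene_list,
                   pair$validation$sepsis_gene_list)
  expect_equal(ncol(pair$validation$expression), 70L)
  expect_false(identical(pair$derivation$expression[, 1],
                         pair$validation$expression[, 1]))
})

test_that("inconsistent cohort parameters are rejected", {
  expect_error(cohort_spec(n_signal_genes = 100, n_genes = 50))
  expect_error(cohort_spec(subtype_proportion = 1))
  expect_error(cohort_spec(delta = -1))
  expect_error(cohort_spec(missing_rate = 1))
})
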