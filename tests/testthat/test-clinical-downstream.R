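test_that("Fisher's exact test reproduces the enumerated two-sided p on a perfect split", {
  clin <- data.frame(sample_id = sprintf("S%02d", 1:10),
                     flag = rep(c(1, 0), each = 5))
  labels <- rep(1:2, each = 5)
  out <- compare_clinical(clin, labels)
  expect_equal(out$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(out$subtype1, 100)
  expect_equal(out$subtype2, 0)
  expect_equal(out$type, "binary")
})

test_that("Fisher p agrees with full-table enumeration for all small margins", {
  set.seed(50)
  for (i in 1:40) {
    tab <- matrix(sample(0:7, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(stats::fisher.test(tab)$p.value, fisher_enum_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("identical continuous distributions give p = 1", {
  clin <- data.frame(sample_id = sprintf("S%02d", 1:8),
                     score = rep(c(1, 2, 3, 4), 2))
  labels <- rep(1:2, each = 4)
  out <- compare_clinical(clin, labels)
  expect_equal(out$type, "continuous")
  expect_equal(out$p_value, 1)
  # constant attribute across the cohort
  clin$flat <- 5
  out2 <- compare_clinical(clin, labels)
  expect_equal(out2$p_value[out2$attribute == "flat"], 1)
  expect_match(out2$note[out2$attribute == "flat"], "variance")
})

test_that("a single-level binary attribute is reported with p = 1 and a note", {
  clin <- data.frame(sample_id = sprintf("S%02d", 1:6), yes = rep(1, 6))
  out <- compare_clinical(clin, rep(1:2, each = 3))
  expect_equal(out$p_value, 1)
  expect_match(out$note, "single level")
})

test_that("the severe-sepsis contrast is detected in nearly all simulated cohorts", {
  set.seed(51)
  hits <- replicate(100, {
    x1 <- rbinom(250, 1, 0.36)
    x2 <- rbinom(250, 1, 0.09)
    clin <- data.frame(sample_id = sprintf("S%03d", 1:500),
                       severe_sepsis = c(x1, x2))
    out <- compare_clinical(clin, rep(1:2, each = 250))
    out$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("fold changes follow the log2 definition and invert under label swap", {
  m <- rbind(gA = c(3, 3, 2, 2), gB = c(4, 4, 4, 4), gC = c(1, 2, 3, 4))
  colnames(m) <- sprintf("S%d", 1:4)
  labels <- c(1, 1, 2, 2)
  fc <- fold_changes(m, labels, c("gA", "gB"))
  expect_equal(fc$fold_change[fc$gene_id == "gA"], 2.0)
  expect_equal(fc$fold_change[fc$gene_id == "gB"], 1.0)
  swapped <- fold_changes(m, 3 - labels, c("gA", "gB", "gC"))
  orig <- fold_changes(m, labels, c("gA", "gB", "gC"))
  expect_equal(orig$fold_change * swapped$fold_change, rep(1, 3),
               tolerance = 1e-10)
  expect_warning(fold_changes(m, labels, c("gA", "gZ")), "gZ")
})

test_that("fold-change tables carry SAM q-values when supplied", {
  set.seed(52)
  m <- expr_mat(rnorm(40 * 12), 40, 12)
  labels <- rep(1:2, each = 6)
  sam <- sam_two_class(m, labels, n_permutations = 50, seed = 1)
  fc <- fold_changes(m, labels, rownames(m)[1:5], sam = sam)
  expect_equal(fc$q_value, unname(sam$q_value[rownames(m)[1:5]]))
})

test_that("over-representation p-values reproduce the hypergeometric enumeration", {
  universe <- sprintf("u%02d", 1:20)
  sets <- list(hit = universe[1:5])
  signature <- universe[1:4]
  out <- overrepresentation(signature, sets, universe)
  expect_equal(out$p_value, 5 / choose(20, 4), tolerance = 1e-12)
  expect_equal(out$overlap, 4L)
  expect_equal(out$bonferroni, out$p_value)   # single set tested
  # random instances against the enumeration oracle
  set.seed(53)
  for (i in 1:20) {
    N <- sample(15:40, 1)
    uni <- sprintf("x%03d", seq_len(N))
    st <- sample(uni, sample(3:10, 1))
    sg <- sample(uni, sample(3:10, 1))
    got <- overrepresentation(sg, list(s = st), uni)
    ov <- length(intersect(sg, st))
    expect_equal(got$p_value, hyper_enum_p(ov, length(st), N, length(sg)),
                 tolerance = 1e-9)
  }
})

test_that("zero overlap with a small set is unremarkable and Bonferroni caps at 1", {
  universe <- sprintf("u%02d", 1:50)
  sets <- list(a = universe[1:3], b = universe[4:6], c = universe[7:9],
               d = universe[10:12], e = universe[13:15])
  signature <- universe[40:45]
  out <- overrepresentation(signature, sets, universe)
  expect_true(all(out$p_value > 0.3))
  expect_true(all(out$bonferroni <= 1))
  expect_equal(out$bonferroni, pmin(1, out$p_value * 5))
})

test_that("hypergeometric p decreases as overlap grows at fixed margins", {
  ps <- vapply(0:5, function(ov) hyper_enum_p(ov, 8, 30, 5), numeric(1))
  expect_true(all(diff(ps) < 0))
  # and the implementation follows suit on constructed signatures
  universe <- sprintf("u%02d", 1:30)
  st <- universe[1:8]
  got <- vapply(2:5, function(ov) {
    sg <- c(universe[seq_len(ov)],
            if (ov < 5) universe[19 + seq_len(5 - ov)])
    overrepresentation(sg, list(s = st), universe)$p_value
  }, numeric(1))
  expect_true(all(diff(got) < 0))
})

test_that("signature genes outside the universe are dropped with a warning", {
  universe <- sprintf("u%02d", 1:20)
  expect_warning(
    out <- overrepresentation(c(universe[1:3], "alien"),
                              list(s = universe[1:5]), universe),
    "outside the universe")
  expect_equal(out$signature_size, 3L)
  expect_error(overrepresentation("a", list(s = "a"), character(0)), "universe")
})
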