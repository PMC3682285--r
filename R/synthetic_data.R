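#' Default clinical attribute specification
#'
#' Subtype-linked clinical attributes emulating an ICU sepsis cohort: binary
#' attributes are Bernoulli with per-subtype prevalence, continuous ones
#' Gaussian with per-subtype means. Defaults reflect the contrasts of a
#' two-subtype adult sepsis cohort (severe sepsis markedly more prevalent in
#' subtype 1: 36% vs 9%; septic shock 44% vs 64%; similar age and APACHE II).
#'
#' @param severe_sepsis,septic_shock Length-2 prevalences (subtype 1, 2).
#' @param age_mean,los_mean,apache_mean Length-2 per-subtype means.
#' @param age_sd,los_sd,apache_sd Common within-subtype SDs.
#' @return List of attribute specs usable as `clinical_spec` in
#'   [cohort_spec()].
#' @export
default_clinical_spec <- function(severe_sepsis = c(0.36, 0.09),
                                  septic_shock = c(0.44, 0.64),
                                  age_mean = c(63, 66), age_sd = 15,
                                  los_mean = c(45, 31), los_sd = 20,
                                  apache_mean = c(19, 19), apache_sd = 6) {
  list(
    list(name = "severe_sepsis", type = "binary", params = severe_sepsis),
    list(name = "septic_shock", type = "binary", params = septic_shock),
    list(name = "age", type = "continuous", params = age_mean, sd = age_sd),
    list(name = "los_days", type = "continuous", params = los_mean, sd = los_sd),
    list(name = "apache_ii", type = "continuous", params = apache_mean, sd = apache_sd)
  )
}

#' Specify a synthetic two-subtype cohort
#'
#' Parameters of the generative model used by [generate_cohort()]: two latent
#' subtypes of unequal size; `n_signal_genes` genes carry a between-subtype
#' shift of `delta` within-subtype standard deviations (so a signal gene is a
#' two-component common-variance Gaussian mixture across samples, population
#' bimodality index `sqrt(p*(1-p)) * delta`); the remaining genes are
#' uninformative noise. Entries are masked missing-at-random at
#' `missing_rate`, with `n_high_missing_samples` samples forced above the 80%
#' missingness filter threshold. A curated candidate gene list is emulated by
#' including `sepsis_gene_fraction` of the signal genes plus an equal number
#' of decoy noise genes.
#'
#' Defaults mirror a derivation cohort of 55 septic ICU patients profiled on
#' 365 literature-derived candidate genes with roughly 10% informative genes
#' and a subtype-1 fraction of 0.4.
#'
#' @param n_samples,n_genes,n_signal_genes Cohort dimensions.
#' @param subtype_proportion Fraction of samples in subtype 1, in (0, 1).
#' @param delta Standardised between-subtype shift of signal genes, in units
#'   of `within_sd` (`delta = 0` generates no subtype structure).
#' @param within_sd Within-subtype SD on the log2 scale.
#' @param missing_rate Per-entry missing-at-random probability in [0, 1).
#' @param n_high_missing_samples Samples forced to >80% missing entries.
#' @param sepsis_gene_fraction Fraction of signal genes placed on the curated
#'   candidate list.
#' @param clinical_spec Attribute specs, see [default_clinical_spec()].
#' @param seed Integer RNG seed; the cohort is deterministic given the spec.
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_samples = 55, n_genes = 365, n_signal_genes = 37,
                        subtype_proportion = 0.4, delta = 3, within_sd = 1,
                        missing_rate = 0.01, n_high_missing_samples = 0,
                        sepsis_gene_fraction = 0.9,
                        clinical_spec = default_clinical_spec(), seed = 1) {
  stopifnot(n_samples >= 4, n_genes >= 2,
            n_signal_genes >= 0, n_signal_genes <= n_genes,
            subtype_proportion > 0, subtype_proportion < 1,
            delta >= 0, within_sd > 0,
            missing_rate >= 0, missing_rate < 1,
            n_high_missing_samples >= 0, n_high_missing_samples < n_samples,
            sepsis_gene_fraction >= 0, sepsis_gene_fraction <= 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_signal_genes = as.integer(n_signal_genes),
                 subtype_proportion = subtype_proportion,
                 delta = delta, within_sd = within_sd,
                 missing_rate = missing_rate,
                 n_high_missing_samples = as.integer(n_high_missing_samples),
                 sepsis_gene_fraction = sepsis_gene_fraction,
                 clinical_spec = clinical_spec,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic microarray-like cohort
#'
#' Draws a cohort from the model described in [cohort_spec()]: signal genes
#' are two-component Gaussian mixtures across samples with subtype means
#' `delta * within_sd` apart (shift direction random per gene, so subtypes
#' show both over- and under-expressed genes), noise genes a single Gaussian;
#' gene baselines are spread around 8 log2 units. Missingness is
#' missing-at-random except for the designated high-missing samples, which
#' have 85% of entries masked. Every gene retains at least one observed value.
#'
#' @param spec A [cohort_spec()].
#' @param gene_params Optional gene-level parameters from a previously
#'   generated cohort (its `gene_params` element), used by
#'   [generate_cohort_pair()] to draw a second cohort from the same
#'   generative model; `NULL` draws them fresh.
#' @return Object of class `"synthetic_cohort"`: a list with `expression`
#'   (genes x samples matrix, `NA` missing), `clinical` (data.frame),
#'   `truth_labels` (named integer vector in \{1, 2\}), `truth_signal_genes`,
#'   `sepsis_gene_list`, and the echoed `spec`.
#' @export
generate_cohort <- function(spec, gene_params = NULL) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec")
  set.seed(spec$seed)
  n <- spec$n_samples
  g <- spec$n_genes
  n1 <- max(1L, min(n - 1L, round(n * spec$subtype_proportion)))
  labels <- sample(rep.int(c(1L, 2L), c(n1, n - n1)))
  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_ids <- sprintf("G%04d", seq_len(g))
  names(labels) <- sample_ids

  if (is.null(gene_params)) {
    signal_idx <- if (spec$n_signal_genes > 0L)
      sort(sample.int(g, spec$n_signal_genes)) else integer(0)
    baseline <- stats::rnorm(g, mean = 8, sd = 1)
    direction <- sample(c(-1, 1), length(signal_idx), replace = TRUE)
    n_list <- round(spec$sepsis_gene_fraction * length(signal_idx))
    listed_signal_idx <- if (n_list > 0L) sample(signal_idx, n_list) else integer(0)
    noise_idx <- setdiff(seq_len(g), signal_idx)
    decoy_idx <- if (n_list > 0L && length(noise_idx))
      sample(noise_idx, min(n_list, length(noise_idx))) else integer(0)
    gene_params <- list(signal_idx = signal_idx, baseline = baseline,
                        direction = direction,
                        sepsis_idx = sort(c(listed_signal_idx, decoy_idx)))
  } else {
    if (length(gene_params$baseline) != g)
      stop("`gene_params` were drawn for a different number of genes")
  }
  signal_idx <- gene_params$signal_idx
  baseline <- gene_params$baseline
  shift <- numeric(g)
  shift[signal_idx] <- gene_params$direction * spec$delta * spec$within_sd
  # subtype 1 gets +shift/2, subtype 2 gets -shift/2 => |mu1 - mu2| = delta*sd
  mu <- outer(baseline, rep(1, n)) +
    outer(shift / 2, ifelse(labels == 1L, 1, -1))
  x <- mu + matrix(stats::rnorm(g * n, sd = spec$within_sd), g, n)
  dimnames(x) <- list(gene_ids, sample_ids)

  mask <- matrix(stats::runif(g * n) < spec$missing_rate, g, n)
  if (spec$n_high_missing_samples > 0L) {
    hi <- sample.int(n, spec$n_high_missing_samples)
    n_mask <- ceiling(0.85 * g)
    for (j in hi) mask[sample.int(g, n_mask), j] <- TRUE
  }
  # keep the imputation precondition: every gene observed somewhere
  dead <- which(rowSums(!mask) == 0L)
  for (i in dead) mask[i, sample.int(n, 1L)] <- FALSE
  x[mask] <- NA_real_

  clin <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  for (att in spec$clinical_spec) {
    p <- att$params
    clin[[att$name]] <- if (att$type == "binary") {
      stats::rbinom(n, 1L, p[labels])
    } else {
      stats::rnorm(n, mean = p[labels], sd = att$sd)
    }
  }

  signal_genes <- gene_ids[signal_idx]
  sepsis_list <- gene_ids[gene_params$sepsis_idx]

  structure(list(expression = x, clinical = clin, truth_labels = labels,
                 truth_signal_genes = signal_genes,
                 sepsis_gene_list = sepsis_list, spec = spec,
                 gene_params = gene_params),
            class = "synthetic_cohort")
}

#' Generate a matched derivation/validation cohort pair
#'
#' Draws two cohorts from the same generative model: gene-level parameters
#' (which genes carry signal, their baselines, shift directions and the
#' curated candidate list) are drawn once under the derivation spec and
#' shared, while samples, missingness and clinical attributes are drawn
#' independently per cohort. This mirrors two independent patient cohorts
#' profiled on the same platform, the setting in which a subtype model
#' learned on the first cohort is transferred to the second by
#' nearest-medoid classification.
#'
#' The two specs must agree on `n_genes`; per the reference setting the
#' validation cohort defaults carry a higher missing rate (5% vs 1%).
#'
#' @param derivation_spec,validation_spec [cohort_spec()]s; the validation
#'   spec defaults to the derivation spec with 70 samples, 5% missingness
#'   and a shifted seed.
#' @return List with elements `derivation` and `validation`, both
#'   `"synthetic_cohort"`s sharing `gene_params`.
#' @export
generate_cohort_pair <- function(derivation_spec = cohort_spec(),
                                 validation_spec = NULL) {
  if (is.null(validation_spec)) {
    validation_spec <- derivation_spec
    validation_spec$n_samples <- 70L
    validation_spec$missing_rate <- 0.05
    validation_spec$seed <- derivation_spec$seed + 1000L
  }
  if (validation_spec$n_genes != derivation_spec$n_genes)
    stop("matched cohorts must share the gene panel (n_genes)")
  derivation <- generate_cohort(derivation_spec)
  validation <- generate_cohort(validation_spec,
                                gene_params = derivation$gene_params)
  list(derivation = derivation, validation = validation)
}

#' Write a synthetic cohort to disk
#'
#' Emits `expression.tsv` (tab-delimited, empty cell = missing),
#' `clinical.csv`, `sepsis_genes.txt` (one symbol per line) and `truth.json`
#' (labels, signal genes and the generating parameters). The expression file
#' round-trips exactly through [read_expression()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param directory Output directory, created if needed.
#' @return Named character vector of the file paths written, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  if (!inherits(cohort, "synthetic_cohort")) stop("`cohort` must be a synthetic_cohort")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(directory, "expression.tsv"),
             clinical = file.path(directory, "clinical.csv"),
             gene_list = file.path(directory, "sepsis_genes.txt"),
             truth = file.path(directory, "truth.json"))
  write_expression(cohort$expression, paths[["expression"]])
  utils::write.csv(cohort$clinical, paths[["clinical"]], row.names = FALSE)
  writeLines(cohort$sepsis_gene_list, paths[["gene_list"]])
  truth <- list(labels = as.list(stats::setNames(as.integer(cohort$truth_labels),
                                                 names(cohort$truth_labels))),
                signal_genes = cohort$truth_signal_genes,
                spec = unclass(cohort$spec)[setdiff(names(cohort$spec), "clinical_spec")])
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
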