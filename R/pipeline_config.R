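#' Pipeline configuration
#'
#' Bundles every tunable of the discovery/validation workflow with the
#' defaults of the reference analysis: cluster numbers swept over 2..10,
#' 100 random-thirds repetitions, a 100-gene enriched subset, 200 SAM
#' permutations, Minkowski exponent 3 for the hierarchical cross-check, 200
#' bootstrap resamples and a bimodality-index threshold of 1.1. A config
#' echo (including the derived per-stage seeds) is attached to results
#' written by [run_discovery()] for provenance.
#'
#' @param k_range,n_reps,subset_fraction,n_outer,n_inner,top_m,n_permutations,minkowski_p,bootstrap_resamples,bi_threshold,seed
#'   See the respective stage functions.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(k_range = 2:10, n_reps = 100,
                            subset_fraction = 1 / 3, n_outer = 100,
                            n_inner = 100, top_m = 100, n_permutations = 200,
                            minkowski_p = 3, bootstrap_resamples = 200,
                            bi_threshold = 1.1, seed = 1) {
  stopifnot(n_reps >= 1, n_outer >= 1, n_inner >= 1, top_m >= 1,
            n_permutations >= 1, bootstrap_resamples >= 1,
            subset_fraction > 0, subset_fraction < 1,
            minkowski_p >= 1, bi_threshold > 0)
  structure(list(k_range = as.integer(k_range), n_reps = as.integer(n_reps),
                 subset_fraction = subset_fraction,
                 n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
                 top_m = as.integer(top_m),
                 n_permutations = as.integer(n_permutations),
                 minkowski_p = minkowski_p,
                 bootstrap_resamples = as.integer(bootstrap_resamples),
                 bi_threshold = bi_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run discovery under a configuration, with optional report output
#'
#' Thin orchestration over [discover_subtypes()]: applies a
#' [pipeline_config()], and when `output_dir` is given writes a
#' machine-readable `model.json` (signature genes and full-precision medoid
#' vectors, plus the config echo) and a human-readable `stages.tsv`
#' provenance table. Inputs are never modified.
#'
#' @param m Imputed genes x samples matrix.
#' @param sepsis_genes Curated candidate gene IDs.
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for report artifacts.
#' @return The `"subtype_discovery"` result (with the config attached).
#' @export
run_discovery <- function(m, sepsis_genes, config = pipeline_config(),
                          output_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config")
  res <- discover_subtypes(m, sepsis_genes,
                           k_range = config$k_range, n_reps = config$n_reps,
                           subset_fraction = config$subset_fraction,
                           n_outer = config$n_outer, n_inner = config$n_inner,
                           top_m = config$top_m,
                           n_permutations = config$n_permutations,
                           minkowski_p = config$minkowski_p,
                           seed = config$seed)
  res$config <- config
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    model <- list(k = res$model$k,
                  signature_genes = res$model$signature_genes,
                  medoids = apply(res$model$medoids, 2L, identity,
                                  simplify = FALSE),
                  medoid_gene_order = rownames(res$model$medoids),
                  config = unclass(config))
    jsonlite::write_json(model, file.path(output_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(res$provenance, file.path(output_dir, "stages.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
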