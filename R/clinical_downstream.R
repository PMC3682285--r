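#' Compare clinical attributes between subtypes
#'
#' Binary attributes are tested with a two-sided Fisher's exact test on the
#' 2x2 subtype-by-attribute table and reported as per-subtype percentages;
#' continuous attributes with a two-sided two-sample Student's t-test
#' (pooled variance by default, Welch by flag) and reported as per-subtype
#' means. Attribute types are taken from logical/0-1 columns (binary) versus
#' numeric columns (continuous) unless given explicitly.
#'
#' @param clinical Data.frame with a `sample_id` column (see
#'   [read_clinical()]).
#' @param labels Named or positional two-subtype labels covering the
#'   clinical table's samples.
#' @param types Optional named character vector (`"binary"` /
#'   `"continuous"`) overriding type inference per attribute.
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   Student's test.
#' @return Data.frame with one row per attribute: `attribute`, `type`,
#'   `subtype1`, `subtype2` (percentage or mean), `p_value` and `note`
#'   (degenerate cases, e.g. an attribute constant across the cohort, get
#'   `p = 1` with a note).
#' @export
compare_clinical <- function(clinical, labels, types = NULL, welch = FALSE) {
  if (!is.data.frame(clinical) || !"sample_id" %in% names(clinical))
    stop("`clinical` must be a data.frame with a sample_id column")
  if (!is.null(names(labels))) {
    miss <- setdiff(clinical$sample_id, names(labels))
    if (length(miss)) stop("labels missing for samples: ",
                           paste(miss, collapse = ", "))
    labels <- labels[clinical$sample_id]
  } else if (length(labels) != nrow(clinical)) {
    stop("`labels` length must match the clinical table")
  }
  lev <- sort(unique(as.vector(labels)))
  if (length(lev) != 2L) stop("clinical comparison needs exactly 2 subtypes")
  g1 <- labels == lev[1L]; g2 <- labels == lev[2L]

  attrs <- setdiff(names(clinical), "sample_id")
  rows <- lapply(attrs, function(a) {
    v <- clinical[[a]]
    type <- if (!is.null(types) && a %in% names(types)) types[[a]]
    else if (is.logical(v) || all(v[!is.na(v)] %in% c(0, 1))) "binary"
    else "continuous"
    note <- ""
    if (type == "binary") {
      v <- as.integer(as.logical(v))
      s1 <- 100 * mean(v[g1], na.rm = TRUE)
      s2 <- 100 * mean(v[g2], na.rm = TRUE)
      if (length(unique(v[!is.na(v)])) < 2L) {
        p <- 1
        note <- "attribute has a single level"
      } else {
        tab <- table(factor(v, levels = c(0, 1)),
                     factor(as.vector(labels), levels = lev))
        p <- stats::fisher.test(tab)$p.value
      }
    } else {
      s1 <- mean(v[g1], na.rm = TRUE)
      s2 <- mean(v[g2], na.rm = TRUE)
      if (stats::sd(v[g1], na.rm = TRUE) == 0 &&
          stats::sd(v[g2], na.rm = TRUE) == 0) {
        p <- if (isTRUE(all.equal(s1, s2))) 1 else 0
        note <- "zero within-subtype variance"
      } else {
        p <- stats::t.test(v[g1], v[g2], var.equal = !welch)$p.value
      }
    }
    data.frame(attribute = a, type = type, subtype1 = s1, subtype2 = s2,
               p_value = p, note = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Between-subtype fold changes
#'
#' On log2 expression, the fold change of subtype 1 over subtype 2 is
#' `FC = 2^(mean1 - mean2)`; values above 1 mean higher expression in
#' subtype 1. Intended for focused gene groups such as pharmacogene sets,
#' where 1.3- to 3-fold between-subtype differences are the biologically
#' interesting range. When a SAM result is supplied its q-values are
#' attached so reporting can be limited to, e.g., q = 0 genes.
#'
#' @param m Imputed genes x samples log2 matrix.
#' @param labels Two-subtype labels over samples.
#' @param genes Gene IDs to report; absent genes are skipped with a warning.
#' @param sam Optional [sam_two_class()] result supplying q-values.
#' @return Data.frame: `gene_id`, `mean_subtype1`, `mean_subtype2`,
#'   `log2_fc`, `fold_change`, and `q_value` when `sam` is given.
#' @export
fold_changes <- function(m, labels, genes, sam = NULL) {
  check_expression_matrix(m, require_complete = TRUE)
  labels <- as.vector(labels)
  if (length(labels) != ncol(m)) stop("`labels` length must match samples")
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("fold changes need exactly 2 subtypes")
  genes <- as.character(genes)
  absent <- setdiff(genes, rownames(m))
  if (length(absent)) {
    warning("genes absent from the matrix skipped: ",
            paste(absent, collapse = ", "))
    genes <- setdiff(genes, absent)
  }
  if (!length(genes)) stop("no requested genes present")
  m1 <- rowMeans(m[genes, labels == lev[1L], drop = FALSE])
  m2 <- rowMeans(m[genes, labels == lev[2L], drop = FALSE])
  out <- data.frame(gene_id = genes, mean_subtype1 = unname(m1),
                    mean_subtype2 = unname(m2), log2_fc = unname(m1 - m2),
                    fold_change = unname(2^(m1 - m2)),
                    stringsAsFactors = FALSE)
  if (!is.null(sam)) {
    if (!inherits(sam, "sam_result")) stop("`sam` must be a sam_result")
    out$q_value <- unname(sam$q_value[genes])
  }
  out
}

#' Over-representation of gene sets in a signature
#'
#' Hypergeometric upper-tail test of whether each gene set overlaps the
#' signature more than expected from a background universe (the statistical
#' form of a pathway over-representation analysis), with Bonferroni
#' correction over the number of sets tested. Signature genes outside the
#' universe are dropped with a warning; set members are intersected with the
#' universe before testing.
#'
#' @param signature Character vector of signature gene IDs.
#' @param sets Named list of gene-ID vectors (see [read_gmt()]).
#' @param universe Character vector: the background gene population
#'   (typically the platform's gene list).
#' @return Data.frame sorted by raw p: `set_name`, `overlap`, `set_size`,
#'   `signature_size`, `universe_size`, `p_value`,
#'   `bonferroni` (`min(1, p * n_sets)`).
#' @export
overrepresentation <- function(signature, sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("`universe` must be non-empty")
  if (!length(sets)) stop("`sets` must contain at least one gene set")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("`sets` must be a named list")
  signature <- unique(as.character(signature))
  outside <- setdiff(signature, universe)
  if (length(outside)) {
    warning(length(outside), " signature genes outside the universe dropped")
    signature <- intersect(signature, universe)
  }
  n_draw <- length(signature)
  n_univ <- length(universe)
  m_tests <- length(sets)
  rows <- lapply(names(sets), function(nm) {
    set_u <- intersect(unique(sets[[nm]]), universe)
    ov <- length(intersect(signature, set_u))
    p <- stats::phyper(ov - 1L, length(set_u), n_univ - length(set_u),
                       n_draw, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, set_size = length(set_u),
               signature_size = n_draw, universe_size = n_univ,
               p_value = p, bonferroni = min(1, p * m_tests),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value, out$set_name), , drop = FALSE]
}
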