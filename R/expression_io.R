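#' @title Expression matrices and file formats
#' @description Expression data are held as plain numeric matrices on the
#'   log2-intensity scale, genes in rows and samples in columns, with `NA`
#'   marking missing entries and unique `rownames()` / `colnames()` carrying
#'   the gene and sample identifiers. All pipeline functions accept and
#'   return this representation.
#' @name expression-matrix
NULL

# Validate the genes x samples matrix contract; returns the matrix invisibly.
check_expression_matrix <- function(m, require_complete = FALSE,
                                    arg = deparse(substitute(m))) {
  if (!is.matrix(m) || !is.numeric(m))
    stop(sprintf("`%s` must be a numeric matrix (genes x samples)", arg))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(sprintf("`%s` must have gene rownames and sample colnames", arg))
  if (anyDuplicated(rownames(m)))
    stop(sprintf("duplicate gene IDs in `%s`: %s", arg,
                 paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")))
  if (anyDuplicated(colnames(m)))
    stop(sprintf("duplicate sample IDs in `%s`: %s", arg,
                 paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")))
  if (require_complete && anyNA(m))
    stop(sprintf("`%s` contains missing values; impute first (see impute_missing())", arg))
  invisible(m)
}

#' Read a tab-delimited expression matrix
#'
#' The expected layout is one header row of sample identifiers (optionally
#' preceded by a gene-ID column header), then one row per gene whose first
#' field is the gene identifier. Empty cells or the literal `NA` are read as
#' missing values.
#'
#' @param path Path to a UTF-8 tab-delimited text file.
#' @return Numeric genes x samples matrix with `NA` for missing entries.
#' @seealso [write_expression()], [impute_missing()]
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression file has no data rows: ", path)
  # sentinel keeps trailing empty (= missing) fields that strsplit drops
  fields <- lapply(strsplit(paste0(lines, "\tEND"), "\t", fixed = TRUE),
                   function(f) f[-length(f)])
  header <- fields[[1L]]
  body <- fields[-1L]
  widths <- lengths(body)
  n_col <- widths[1L]
  bad <- which(widths != n_col)
  if (length(bad))
    stop(sprintf("ragged expression file %s: line %d has %d fields, expected %d",
                 path, bad[1L] + 1L, widths[bad[1L]], n_col))
  sample_ids <- if (length(header) == n_col) header[-1L] else header
  if (length(sample_ids) != n_col - 1L)
    stop(sprintf("header of %s has %d sample IDs but rows have %d value fields",
                 path, length(sample_ids), n_col - 1L))
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  raw <- vapply(body, function(f) f[-1L], character(n_col - 1L))
  raw <- if (is.null(dim(raw))) matrix(raw, nrow = 1L) else t(raw)
  raw[raw == "" | raw == "NA"] <- NA_character_
  values <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (any(is.na(values) & !is.na(raw)))
    stop("non-numeric expression values in ", path)
  dimnames(values) <- list(gene_ids, sample_ids)
  check_expression_matrix(values)
}

#' Write an expression matrix to tab-delimited text
#'
#' Missing entries are written as empty cells. Values are written with full
#' double precision so a write/read round trip reproduces the matrix exactly.
#'
#' @param m Genes x samples numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  check_expression_matrix(m)
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- ""
    out
  }
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"), character(1))
  writeLines(c(paste(c("gene_id", colnames(m)), collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is `set_name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of member gene IDs; the
#'   description lines are kept in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d of %s has fewer than 3 fields", short[1L], path))
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set names in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[[`, character(1), 2L), nms)
  sets
}

#' Read a clinical attribute table
#'
#' A CSV with a `sample_id` column and one column per clinical attribute;
#' binary attributes coded 0/1 or TRUE/FALSE, continuous attributes numeric.
#'
#' @param path Path to a CSV file.
#' @return `data.frame` with a `sample_id` character column first.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("clinical table lacks a sample_id column: ", path)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs in clinical table ", path)
  df$sample_id <- as.character(df$sample_id)
  df[c("sample_id", setdiff(names(df), "sample_id"))]
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines dropped, duplicates removed keeping the
#' first occurrence (curated symbol lists commonly contain repeats).
#'
#' @param path Path to a text file.
#' @return Character vector of unique gene IDs.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path, encoding = "UTF-8"))
  unique(x[nzchar(x)])
}

#' Remove samples exceeding a missing-data threshold
#'
#' Drops every sample whose fraction of missing entries is strictly greater
#' than `threshold` (default 80%, the level at which one validation-cohort
#' patient was excluded in the motivating study design). A sample at exactly
#' the threshold is retained. Filtering is idempotent and order-stable.
#'
#' @param m Genes x samples matrix with `NA` for missing values.
#' @param threshold Missing fraction above which a sample is removed,
#'   in (0, 1).
#' @return List with `matrix` (filtered) and `removed` (dropped sample IDs).
#' @export
filter_high_missing_samples <- function(m, threshold = 0.80) {
  check_expression_matrix(m)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("`threshold` must be a single fraction in (0, 1)")
  frac <- colMeans(is.na(m))
  drop <- frac > threshold
  if (all(drop))
    stop("all samples exceed the missingness threshold; nothing left to analyse")
  list(matrix = m[, !drop, drop = FALSE], removed = colnames(m)[drop])
}

#' Impute missing expression values
#'
#' Replaces each missing entry by the median of that gene's observed values;
#' observed values are unchanged, so per-gene medians of observed data are
#' preserved.
#'
#' @param m Genes x samples matrix.
#' @param method Imputation method; only `"gene_median"` is implemented.
#' @return Matrix with no missing values.
#' @export
impute_missing <- function(m, method = c("gene_median")) {
  method <- match.arg(method)
  check_expression_matrix(m)
  all_missing <- rowSums(!is.na(m)) == 0L
  if (any(all_missing))
    stop("genes with no observed values cannot be imputed: ",
         paste(rownames(m)[all_missing], collapse = ", "))
  if (!anyNA(m)) return(m)
  for (i in which(rowSums(is.na(m)) > 0L)) {
    v <- m[i, ]
    m[i, is.na(v)] <- stats::median(v, na.rm = TRUE)
  }
  m
}

#' Restrict an expression matrix to a candidate gene list
#'
#' Subsets rows to the listed genes in list order, silently dropping list
#' members absent from the platform (mirroring the reduction of a literature
#' search's 450 candidates to the 365 present on the array). Duplicate list
#' entries are deduplicated keeping the first occurrence.
#'
#' @param m Genes x samples matrix.
#' @param genes Character vector of candidate gene IDs.
#' @return Row-subset matrix; the counts of requested and found genes are in
#'   attributes `"n_requested"` and `"n_found"`.
#' @export
restrict_to_gene_list <- function(m, genes) {
  check_expression_matrix(m)
  genes <- unique(as.character(genes))
  found <- genes[genes %in% rownames(m)]
  if (!length(found))
    stop("none of the ", length(genes), " candidate genes are on the platform")
  out <- m[found, , drop = FALSE]
  attr(out, "n_requested") <- length(genes)
  attr(out, "n_found") <- length(found)
  out
}
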