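#' Preprocessing configuration
#'
#' @param variance_threshold Genes with raw variance strictly below this
#'   value are removed (default 0.1, the pipeline's filtering threshold).
#' @param iqr_zero_policy Handling of genes whose interquartile range is
#'   zero under robust scaling: `"zeros"` (default) maps them to all-zero
#'   columns; `"skip_gene"` drops them.
#' @param ddof Degrees-of-freedom convention for standardization and the
#'   QC report (0 = population, the default, so post-hoc SDs are exactly 1).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(variance_threshold = 0.1,
                              iqr_zero_policy = c("zeros", "skip_gene"),
                              ddof = 0L) {
  if (variance_threshold < 0) abort("`variance_threshold` must be >= 0.")
  if (!ddof %in% c(0L, 1L)) abort("`ddof` must be 0 or 1.")
  structure(list(variance_threshold = variance_threshold,
                 iqr_zero_policy = match.arg(iqr_zero_policy),
                 ddof = as.integer(ddof)),
            class = "preprocess_config")
}

#' Remove low-variance genes
#'
#' Drops genes whose sample variance (population convention, ddof = 0,
#' computed on the values as given) is strictly below `threshold`;
#' survivors keep their order. A gene with variance exactly equal to the
#' threshold is retained.
#'
#' @param m Numeric samples x genes matrix.
#' @param threshold Non-negative variance cutoff (default 0.1).
#' @return The filtered matrix.
#' @export
filter_low_variance <- function(m, threshold = 0.1) {
  assert_expression_matrix(m)
  if (threshold < 0) abort("`threshold` must be >= 0.")
  keep <- col_vars(m) >= threshold
  out <- m[, keep, drop = FALSE]
  region_of(out) <- region_of(m)
  out
}

#' Robust-scale each gene by median and interquartile range
#'
#' Per gene: `(x - median) / IQR`, with the IQR computed as the 75th minus
#' 25th percentile under linear interpolation. Genes with zero IQR are
#' handled per `iqr_zero_policy`.
#'
#' @param m Numeric samples x genes matrix.
#' @param iqr_zero_policy `"zeros"` (zero out constant genes) or
#'   `"skip_gene"` (drop them).
#' @return The scaled matrix (per-gene median 0 for non-degenerate genes).
#' @export
robust_scale <- function(m, iqr_zero_policy = c("zeros", "skip_gene")) {
  assert_expression_matrix(m)
  iqr_zero_policy <- match.arg(iqr_zero_policy)
  q <- apply(m, 2L, quantile, probs = c(0.25, 0.5, 0.75), names = FALSE,
             type = 7L)
  iqr <- q[3L, ] - q[1L, ]
  med <- q[2L, ]
  zero <- iqr == 0
  if (any(zero) && iqr_zero_policy == "skip_gene") {
    m <- m[, !zero, drop = FALSE]
    med <- med[!zero]; iqr <- iqr[!zero]; zero <- zero[!zero]
  }
  scaled <- sweep(m, 2L, med, `-`)
  denom <- ifelse(zero, 1, iqr)
  scaled <- sweep(scaled, 2L, denom, `/`)
  if (any(zero)) scaled[, zero] <- 0
  region_of(scaled) <- region_of(m)
  scaled
}

#' Z-score standardize each gene
#'
#' Per gene: `(x - mean) / sd`, with the SD under the `ddof` convention.
#' Zero-variance columns pass through as all zeros.
#'
#' @param m Numeric samples x genes matrix.
#' @param ddof 0 (population SD, default) or 1 (sample SD).
#' @return The standardized matrix: per-gene mean 0 and SD 1 (within
#'   numerical tolerance), except all-zero columns.
#' @export
zscore <- function(m, ddof = 0L) {
  assert_expression_matrix(m)
  if (!ddof %in% c(0L, 1L)) abort("`ddof` must be 0 or 1.")
  mu <- colMeans(m)
  s <- col_sds(m, ddof = ddof)
  zero <- s == 0
  out <- sweep(m, 2L, mu, `-`)
  out <- sweep(out, 2L, ifelse(zero, 1, s), `/`)
  if (any(zero)) out[, zero] <- 0
  region_of(out) <- region_of(m)
  out
}

#' Aggregate genes with duplicate identifiers
#'
#' Columns sharing a gene ID are replaced by their element-wise mean; the
#' resulting IDs are unique and keep first-occurrence order.
#'
#' @param m Numeric samples x genes matrix (possibly duplicated column
#'   names).
#' @return The aggregated matrix.
#' @export
aggregate_duplicates <- function(m) {
  assert_expression_matrix(m)
  ids <- colnames(m)
  if (!anyDuplicated(ids)) return(m)
  uniq <- unique(ids)
  out <- vapply(uniq, function(id) {
    cols <- which(ids == id)
    if (length(cols) == 1L) m[, cols] else rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), uniq))
  region_of(out) <- region_of(m)
  out
}

#' Run the full preprocessing chain on a region matrix
#'
#' Applies, in order: low-variance filter, robust scaling, Z-score
#' standardization, then duplicate-ID aggregation. The QC metrics (mean of
#' per-gene means, mean of per-gene SDs) are computed on the standardized
#' matrix *before* aggregation, since averaging standardized columns
#' changes their variances.
#'
#' @param m Raw samples x genes matrix.
#' @param cfg A [preprocess_config()].
#' @return A list with `matrix` (the preprocessed matrix) and `qc`, a
#'   one-row tibble: `region`, `mean_of_means`, `mean_of_sds`,
#'   `n_genes_in`, `n_genes_filtered`, `n_duplicates_merged`,
#'   `n_genes_out`.
#' @export
run_preprocessing <- function(m, cfg = preprocess_config()) {
  assert_expression_matrix(m)
  n_in <- ncol(m)
  filtered <- filter_low_variance(m, cfg$variance_threshold)
  if (ncol(filtered) == 0L) {
    abort("No genes remain after low-variance filtering.")
  }
  scaled <- robust_scale(filtered, cfg$iqr_zero_policy)
  standardized <- zscore(scaled, cfg$ddof)
  qc_means <- mean(colMeans(standardized))
  qc_sds <- mean(col_sds(standardized, ddof = cfg$ddof))
  aggregated <- aggregate_duplicates(standardized)
  qc <- tibble::tibble(
    region = region_of(m),
    mean_of_means = qc_means,
    mean_of_sds = qc_sds,
    n_genes_in = n_in,
    n_genes_filtered = n_in - ncol(filtered),
    n_duplicates_merged = ncol(standardized) - ncol(aggregated),
    n_genes_out = ncol(aggregated))
  list(matrix = aggregated, qc = qc)
}
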