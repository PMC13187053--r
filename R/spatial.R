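#' Build a genes x regions importance matrix for one stage
#'
#' Assembles per-region importance vectors into a dense genes x regions
#' matrix (union of genes, zeros for genes absent from a region).
#'
#' @param importance_by_region Named list (region -> importance tibble
#'   with `gene`, `importance`).
#' @return Numeric genes x regions matrix with
#'   `attr(, "state") == "raw"`.
#' @export
gene_region_matrix <- function(importance_by_region) {
  stopifnot(length(importance_by_region) > 0L, !is.null(names(importance_by_region)))
  genes <- sort(unique(unlist(lapply(importance_by_region, `[[`, "gene"))))
  m <- matrix(0, nrow = length(genes), ncol = length(importance_by_region),
              dimnames = list(genes, names(importance_by_region)))
  for (r in names(importance_by_region)) {
    iv <- importance_by_region[[r]]
    m[iv$gene, r] <- iv$importance
  }
  attr(m, "state") <- "raw"
  m
}

#' Row-normalize a genes x regions importance matrix
#'
#' Divides every gene's row by its maximum, so each gene's most responsive
#' region scores exactly 1; all-zero rows stay zero. Negative entries are
#' an error (importances are magnitudes).
#'
#' @param m Non-negative genes x regions matrix.
#' @return The row-normalized matrix, `attr(, "state") == "row_normalized"`.
#' @export
row_normalize <- function(m) {
  if (any(m < 0)) abort("Importances must be non-negative.")
  mx <- apply(m, 1L, max)
  out <- m / ifelse(mx == 0, 1, mx)
  attr(out, "state") <- "row_normalized"
  out
}

#' Stage-level regional importance profile
#'
#' Averages row-normalized importances over genes per region, then applies
#' a final min-max normalization across regions so profiles are comparable
#' between stages (the radar-plot values). A constant mean vector maps to
#' all zeros with a warning.
#'
#' @param m Row-normalized genes x regions matrix (from [row_normalize()]).
#' @return Tibble with `region`, `mean_importance` (raw column mean), and
#'   `profile` (min-max across regions, attaining 0 and 1 unless constant).
#' @export
stage_region_profile <- function(m) {
  if (!identical(attr(m, "state", exact = TRUE), "row_normalized")) {
    abort("`m` must be row-normalized; see row_normalize().")
  }
  if (ncol(m) < 2L) abort("At least 2 regions are required for min-max.")
  mu <- colMeans(m)
  rng <- range(mu)
  profile <- if (diff(rng) == 0) {
    warn("Constant regional means; profile set to zeros.")
    rep(0, length(mu))
  } else {
    (mu - rng[1L]) / diff(rng)
  }
  tibble::tibble(region = colnames(m), mean_importance = unname(mu),
                 profile = unname(profile))
}

#' Cross-stage overlap of top gene lists
#'
#' Quantifies how much the per-stage top-k gene lists share: total
#' selections, unique genes, genes selected in more than one stage, the
#' overlap fraction (multi-stage genes over total selections), and
#' pairwise intersections.
#'
#' @param top_lists Named list of per-stage gene ID vectors; duplicates
#'   within one list are an error.
#' @return List with `n_selected`, `n_unique`, `n_multi_stage`,
#'   `overlap_fraction`, and `pairwise` (tibble with `stage_a`, `stage_b`,
#'   `n_shared`, `shared`).
#' @export
cross_stage_overlap <- function(top_lists) {
  stopifnot(length(top_lists) >= 2L)
  for (nm in names(top_lists)) {
    if (anyDuplicated(top_lists[[nm]])) {
      abort(sprintf("Duplicate gene within list '%s'.", nm))
    }
  }
  all_genes <- unlist(top_lists, use.names = FALSE)
  n_selected <- length(all_genes)
  tab <- table(all_genes)
  n_multi <- sum(tab > 1L)
  pairs <- utils::combn(names(top_lists), 2L, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    shared <- intersect(top_lists[[pr[1L]]], top_lists[[pr[2L]]])
    tibble::tibble(stage_a = pr[1L], stage_b = pr[2L],
                   n_shared = length(shared),
                   shared = paste(shared, collapse = ";"))
  })
  list(n_selected = n_selected,
       n_unique = length(tab),
       n_multi_stage = n_multi,
       overlap_fraction = n_multi / n_selected,
       pairwise = pairwise)
}

#' Stage heatmap table of top genes across regions
#'
#' Builds the genes x regions table behind the per-stage heatmaps: each
#' region's importances are min-max normalized within the region, the row
#' universe is the union of per-region top-k gene lists restricted to the
#' overall top-k by summed normalized importance, rows are sorted by
#' overall importance descending and columns (regions) by their summed
#' importance, ties broken by ID.
#'
#' @param importance_by_region Named list (region -> importance tibble).
#' @param k Top-list size (default 20).
#' @return Numeric genes x regions matrix, sorted, values in `[0, 1]`.
#' @export
heatmap_table <- function(importance_by_region, k = 20L) {
  normed <- lapply(importance_by_region, minmax_normalize)
  m <- gene_region_matrix(normed)
  top_union <- unique(unlist(lapply(normed, top_k_genes, k = k)))
  m <- m[rownames(m) %in% top_union, , drop = FALSE]
  overall <- rowSums(m)
  keep <- head(order(-overall, rownames(m)), k)
  m <- m[keep, , drop = FALSE]
  col_order <- order(-colSums(m), colnames(m))
  m <- m[, col_order, drop = FALSE]
  attr(m, "state") <- "minmax_by_region"
  m
}

#' Co-expression of a biomarker with a pathway panel in one region
#'
#' Spearman correlations between a biomarker gene and every panel gene
#' present in the expression matrix, over samples where both genes are
#' observed. Pairs with fewer than `min_overlap` overlapping samples are
#' skipped (and not counted as tested); a pair is significant when its
#' two-sided p-value is below `alpha`. P-values use the exact null
#' distribution for n <= 10 without ties and the t approximation
#' otherwise (average ranks under ties).
#'
#' @param expr Preprocessed samples x genes matrix with unique gene IDs.
#' @param biomarker Gene ID present in `expr` (error otherwise).
#' @param panel A [pathway_panel()].
#' @param min_overlap Minimum overlapping samples per pair (default 5).
#' @param alpha Significance threshold (default 0.05).
#' @param details If `TRUE`, also return the per-pair table.
#' @return A one-row tibble: `gene`, `region`, `pathway`, `n_tested`,
#'   `n_significant`, `mean_abs_rho`, `max_rho`, `min_rho` (signed
#'   extrema). With `details = TRUE`, a list with `summary` and `pairs`.
#' @export
coexpression_summary <- function(expr, biomarker, panel, min_overlap = 5L,
                                 alpha = 0.05, details = FALSE) {
  assert_expression_matrix(expr, "expr")
  if (!biomarker %in% colnames(expr)) {
    abort(sprintf("Biomarker '%s' absent from the expression matrix.",
                  biomarker))
  }
  candidates <- setdiff(intersect(panel$gene_ids, colnames(expr)), biomarker)
  x <- expr[, biomarker]
  pairs <- purrr::map_dfr(candidates, function(g) {
    yv <- expr[, g]
    ok <- stats::complete.cases(x, yv)
    if (sum(ok) < min_overlap) return(NULL)
    ct <- spearman_test(x[ok], yv[ok])
    tibble::tibble(panel_gene = g, n = sum(ok), rho = ct$rho, p = ct$p)
  })
  summary <- tibble::tibble(
    gene = biomarker,
    region = region_of(expr),
    pathway = panel$panel_name,
    n_tested = nrow(pairs),
    n_significant = if (nrow(pairs)) sum(pairs$p < alpha) else 0L,
    mean_abs_rho = if (nrow(pairs)) mean(abs(pairs$rho)) else NA_real_,
    max_rho = if (nrow(pairs)) max(pairs$rho) else NA_real_,
    min_rho = if (nrow(pairs)) min(pairs$rho) else NA_real_)
  if (details) list(summary = summary, pairs = pairs) else summary
}

# Two-sided Spearman test: exact for small tie-free samples, t
# approximation otherwise.
spearman_test <- function(x, y) {
  n <- length(x)
  ties <- anyDuplicated(x) || anyDuplicated(y)
  exact <- n <= 10L && !ties
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = exact,
             alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
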