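#' Exact Shapley attributions for a trained staging model
#'
#' Computes exact, path-dependent tree-ensemble Shapley values (the
#' TreeExplainer algorithm, as implemented inside xgboost) for every
#' sample, gene, and stage class. Attributions are on the margin
#' (log-odds) scale feeding the softmax, the exact-tree-explainer
#' convention; per sample and class they satisfy local accuracy: base
#' value + sum of gene attributions = the model's margin output.
#'
#' @param model A `stage_model`.
#' @param X Samples x genes matrix; gene order must match the model's
#'   fit-time order.
#' @return An `attribution_tensor`: list with `values` (array samples x
#'   genes x classes), `base_values` (length-3 expected margins),
#'   `gene_ids`, `sample_ids`.
#' @export
compute_attributions <- function(model, X) {
  check_gene_order(model, X)
  d <- xgboost::xgb.DMatrix(X, nthread = model$hp$nthread)
  contrib <- predict(model$booster, d, predcontrib = TRUE)
  # contrib: [samples, classes, genes + bias]
  p <- length(model$gene_ids)
  values <- aperm(contrib[, , seq_len(p), drop = FALSE], c(1L, 3L, 2L))
  dimnames(values) <- list(rownames(X), model$gene_ids,
                           STAGE_LEVELS)
  structure(list(values = values,
                 base_values = contrib[1L, , p + 1L],
                 gene_ids = model$gene_ids,
                 sample_ids = rownames(X)),
            class = "attribution_tensor")
}

#' @export
print.attribution_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<attribution_tensor> %d samples x %d genes x %d classes\n",
              d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Mean absolute Shapley importance per gene for one stage
#'
#' The global importance of each gene for one stage class: the mean of the
#' absolute Shapley attributions over a sample subset (all samples by
#' default). Applied to training samples this is the train importance;
#' applied to held-out test samples it is the test importance used by the
#' confidence framework.
#'
#' @param att An `attribution_tensor`.
#' @param stage Stage class: 0/1/2 or `"Early"/"Mid"/"Late"`.
#' @param samples Optional subset of samples (indices or IDs); must be
#'   non-empty.
#' @return An importance tibble (`gene`, `importance`) with
#'   `attr(, "scale") == "raw"`; invariant to sample order.
#' @export
mean_abs_importance <- function(att, stage, samples = NULL) {
  stopifnot(inherits(att, "attribution_tensor"))
  s <- stage_index(stage)
  v <- att$values[, , s, drop = FALSE][, , 1L]
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L, dimnames = list(att$sample_ids, att$gene_ids))
  if (!is.null(samples)) {
    v <- v[samples, , drop = FALSE]
  }
  if (nrow(v) == 0L) abort("Sample subset is empty.")
  iv <- tibble::tibble(gene = att$gene_ids,
                       importance = unname(colMeans(abs(v))))
  attr(iv, "scale") <- "raw"
  attr(iv, "stage") <- STAGE_LEVELS[s]
  iv
}

stage_index <- function(stage) {
  if (is.character(stage)) {
    s <- match(stage, STAGE_LEVELS)
    if (is.na(s)) abort(sprintf("Unknown stage '%s'.", stage))
    return(s)
  }
  s <- as.integer(stage) + 1L
  if (s < 1L || s > 3L) abort("Stage must be 0, 1 or 2.")
  s
}

#' Top-k genes by importance
#'
#' Genes ordered by descending importance; ties broken by ascending gene
#' ID so the ranking is stable and reproducible.
#'
#' @param iv Importance tibble (`gene`, `importance`).
#' @param k Number of genes (default 20); `k > nrow(iv)` returns all.
#' @return Character vector of gene IDs.
#' @export
top_k_genes <- function(iv, k = 20L) {
  if (k < 1L) abort("`k` must be >= 1.")
  ord <- order(-iv$importance, iv$gene)
  head(iv$gene[ord], k)
}

#' Select high-importance genes from a normalized importance vector
#'
#' Two selection rules: `"threshold"` keeps genes with min-max-normalized
#' importance at or above 0.8 (the rule behind the regional
#' high-importance counts), and `"percentile"` keeps genes strictly above
#' the 90th percentile of the stage-specific importance distribution. The
#' input must be min-max normalized (see [minmax_normalize()]); raw input
#' is an error.
#'
#' @param iv Min-max-normalized importance tibble.
#' @param mode `"threshold"` (default) or `"percentile"`.
#' @param cutoff Threshold value (default 0.8) or percentile (default 0.9).
#' @return Character vector of selected gene IDs.
#' @export
select_high_importance <- function(iv, mode = c("threshold", "percentile"),
                                   cutoff = NULL) {
  mode <- match.arg(mode)
  if (!identical(attr(iv, "scale", exact = TRUE), "minmax")) {
    abort("`iv` must be min-max normalized; see minmax_normalize().")
  }
  if (nrow(iv) == 0L) return(character(0))
  if (mode == "threshold") {
    cutoff <- cutoff %||% 0.8
    iv$gene[iv$importance >= cutoff]
  } else {
    cutoff <- cutoff %||% 0.9
    iv$gene[iv$importance > quantile(iv$importance, cutoff, names = FALSE)]
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
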