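#' Min-max normalize an importance vector
#'
#' `(x - min) / (max - min)` within the vector; a constant vector maps to
#' all zeros. This is the normalization (the tilde) feeding the composite
#' validation score and the high-importance selection rules.
#'
#' @param iv Importance tibble (`gene`, `importance`).
#' @return The tibble with importances in `[0, 1]` and
#'   `attr(, "scale") == "minmax"`.
#' @export
minmax_normalize <- function(iv) {
  rng <- range(iv$importance)
  iv$importance <- if (diff(rng) == 0) {
    rep(0, nrow(iv))
  } else {
    (iv$importance - rng[1L]) / diff(rng)
  }
  attr(iv, "scale") <- "minmax"
  iv
}

#' Composite gene validation score
#'
#' Weighted combination of normalized training importance, normalized test
#' importance, and cross-validation stability:
#' `0.4 * train + 0.3 * test + 0.3 * stability`. Training importance gets
#' the slightly higher weight because it reflects the global contribution
#' learned during optimization; test importance captures generalization to
#' unseen samples; stability rewards reproducible selection across folds.
#' All inputs must be in `[0, 1]`, so the score is too.
#'
#' @param train_norm,test_norm Min-max-normalized importances in `[0, 1]`.
#' @param stability Stability score in `[0, 1]`.
#' @return Numeric validation scores.
#' @export
validation_score <- function(train_norm, test_norm, stability) {
  for (v in list(train_norm, test_norm, stability)) {
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      abort("All validation-score inputs must be in [0, 1].")
    }
  }
  0.4 * train_norm + 0.3 * test_norm + 0.3 * stability
}

#' Assign a confidence tier to genes
#'
#' Tiers combine cross-validation stability with the gene's position in
#' the (region, stage) test-importance distribution:
#' * High: stability >= 0.8 and test importance strictly above the 75th
#'   percentile;
#' * Medium: stability >= 0.6 and test importance strictly above the
#'   median;
#' * Low: stability >= 0.4, regardless of importance;
#' * Excluded otherwise.
#' Percentiles use linear interpolation over the supplied distribution.
#'
#' @param stability Stability scores in `[0, 1]`.
#' @param test_importance Raw test importances, same length.
#' @param distribution The full test-importance distribution of the
#'   (region, stage) against which percentiles are computed; must be
#'   non-empty.
#' @return Factor with levels High, Medium, Low, Excluded.
#' @export
assign_confidence <- function(stability, test_importance, distribution) {
  if (length(distribution) == 0L) {
    abort("`distribution` must be non-empty.")
  }
  q75 <- quantile(distribution, 0.75, names = FALSE)
  q50 <- quantile(distribution, 0.50, names = FALSE)
  tier <- dplyr::case_when(
    stability >= 0.8 & test_importance > q75 ~ "High",
    stability >= 0.6 & test_importance > q50 ~ "Medium",
    stability >= 0.4 ~ "Low",
    TRUE ~ "Excluded")
  factor(tier, levels = CONFIDENCE_LEVELS)
}

#' Cross-validation stability of per-stage gene importance
#'
#' Runs K-fold stratified cross-validation of the entire pipeline: on each
#' fold's training part, SMOTE balancing, model training, Shapley
#' attribution, and extraction of the per-stage top-k genes. A gene's
#' stability for a stage is the fraction of folds in which it appears in
#' that stage's top-k list; the mean rank (over folds where it appears)
#' and the variance of its fold importances are recorded alongside.
#'
#' @param X Samples x genes matrix (preprocessed).
#' @param y Stage labels in `{0, 1, 2}`.
#' @param K Number of folds (default 5).
#' @param k_top Top-list size defining an "appearance" (default 20).
#' @param hp A [stage_hyperparams()].
#' @param seed Master seed; folds and per-fold sub-seeds derive from it.
#' @param detail If `TRUE`, also return the per-fold top-k lists the
#'   stability fractions are counted from.
#' @return Tibble with `gene`, `stage`, `stability`, `mean_rank`,
#'   `importance_variance` for every gene x stage combination; with
#'   `detail = TRUE`, a list with `records` and `fold_top` (fold x stage
#'   top-k gene lists).
#' @export
cv_stability <- function(X, y, K = 5L, k_top = 20L,
                         hp = stage_hyperparams(), seed = 1L,
                         detail = FALSE) {
  folds <- stratified_folds(y, K, seed)
  genes <- colnames(X)
  appear <- array(FALSE, c(length(genes), 3L, K),
                  dimnames = list(genes, STAGE_LEVELS, NULL))
  ranks <- array(NA_real_, c(length(genes), 3L, K))
  imps <- array(NA_real_, c(length(genes), 3L, K))
  fold_top <- list()
  for (k in seq_len(K)) {
    tr <- which(folds != k)
    sub_seed <- derive_seed(seed, "fold", k)
    bal <- smote_balance(X[tr, , drop = FALSE], y[tr], seed = sub_seed)
    hp_k <- hp
    hp_k$seed <- sub_seed
    model <- train_classifier(bal$X, bal$y, hp_k)
    att <- compute_attributions(model, bal$X)
    fold_top[[k]] <- list()
    for (s in 0:2) {
      iv <- mean_abs_importance(att, s)
      imps[, s + 1L, k] <- iv$importance
      ord <- order(-iv$importance, iv$gene)
      ranks[ord, s + 1L, k] <- seq_along(ord)
      top <- top_k_genes(iv, k_top)
      fold_top[[k]][[STAGE_LEVELS[s + 1L]]] <- top
      appear[top, s + 1L, k] <- TRUE
    }
  }
  records <- purrr::map_dfr(1:3, function(s) {
    ap <- appear[, s, , drop = FALSE][, 1L, ]
    if (is.null(dim(ap))) ap <- matrix(ap, ncol = K)
    rk <- matrix(ranks[, s, ], ncol = K)
    im <- matrix(imps[, s, ], ncol = K)
    rk_in <- rk
    rk_in[!ap] <- NA_real_
    tibble::tibble(
      gene = genes,
      stage = STAGE_LEVELS[s],
      stability = unname(rowSums(ap)) / K,
      mean_rank = unname(rowMeans(rk_in, na.rm = TRUE)),
      importance_variance = unname(apply(im, 1L, var)))
  })
  if (detail) list(records = records, fold_top = fold_top) else records
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into K folds.
stratified_folds <- function(y, K, seed) {
  counts <- table(y)
  if (any(counts < K)) {
    abort(sprintf("Every class needs >= %d samples for %d-fold CV.", K, K))
  }
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(K), length(idx))
    }
  })
  folds
}

#' Full gene-confidence framework for one region
#'
#' Runs the complete multi-layer validation for one region's dataset:
#' stratified 70/30 split, K-fold stability on the training split, final
#' SMOTE-balanced model, Shapley importances on the balanced training set
#' and the untouched test set, per-stage min-max normalization, composite
#' validation score, and confidence tier assignment.
#'
#' @param X Preprocessed samples x genes matrix.
#' @param y Stage labels in `{0, 1, 2}`.
#' @param hp A [stage_hyperparams()].
#' @param K,k_top Stability parameters (defaults 5 and 20).
#' @param train_frac Training fraction for the outer split (default 0.7).
#' @param seed Master seed.
#' @return A `gene_confidence` tibble with one row per gene x stage:
#'   `gene`, `stage`, `train_importance_raw`, `test_importance_raw`,
#'   `train_norm`, `test_norm`, `stability`, `validation_score`,
#'   `confidence`; the fitted model's test performance is attached as
#'   `attr(, "performance")`.
#' @export
gene_confidence <- function(X, y, hp = stage_hyperparams(), K = 5L,
                            k_top = 20L, train_frac = 0.7, seed = 1L) {
  split <- stratified_split(y, train_frac, seed = derive_seed(seed, "split"))
  X_tr <- X[split$train, , drop = FALSE]
  y_tr <- y[split$train]
  X_te <- X[split$test, , drop = FALSE]
  y_te <- y[split$test]

  stab <- cv_stability(X_tr, y_tr, K = K, k_top = k_top, hp = hp,
                       seed = derive_seed(seed, "cv"))

  bal <- smote_balance(X_tr, y_tr, seed = derive_seed(seed, "smote"))
  hp_fit <- hp
  hp_fit$seed <- derive_seed(seed, "fit")
  model <- train_classifier(bal$X, bal$y, hp_fit)
  att_train <- compute_attributions(model, bal$X)
  att_test <- compute_attributions(model, X_te)

  out <- purrr::map_dfr(0:2, function(s) {
    iv_tr <- mean_abs_importance(att_train, s)
    iv_te <- mean_abs_importance(att_test, s)
    tibble::tibble(
      gene = iv_tr$gene,
      stage = STAGE_LEVELS[s + 1L],
      train_importance_raw = iv_tr$importance,
      test_importance_raw = iv_te$importance,
      train_norm = minmax_normalize(iv_tr)$importance,
      test_norm = minmax_normalize(iv_te)$importance)
  })
  out <- dplyr::left_join(out, stab, by = c("gene", "stage"))
  out$validation_score <- validation_score(out$train_norm, out$test_norm,
                                           out$stability)
  out <- out |>
    dplyr::group_by(.data$stage) |>
    dplyr::mutate(confidence = assign_confidence(
      .data$stability, .data$test_importance_raw,
      .data$test_importance_raw)) |>
    dplyr::ungroup()
  attr(out, "performance") <- evaluate(model, X_te, y_te)
  attr(out, "model") <- model
  class(out) <- c("gene_confidence", class(out))
  out
}

#' Permutation significance of gene importance
#'
#' The observed statistic for each gene is the maximum over stages of its
#' mean absolute Shapley attribution from the real fit. The null
#' distribution re-runs the full pipeline (SMOTE balancing, training,
#' attribution on the same samples) under B stage-label permutations; the
#' p-value uses the add-one estimator `(1 + #{null >= observed}) / (B + 1)`
#' so it can never be zero, and Benjamini-Hochberg correction yields
#' q-values, with significance declared at `q < alpha`.
#'
#' @param X Samples x genes matrix (preprocessed).
#' @param y Stage labels.
#' @param B Number of label permutations; at least 19 (coarser p-value
#'   resolution is refused).
#' @param hp A [stage_hyperparams()].
#' @param seed Master seed.
#' @param alpha FDR threshold (default 0.005).
#' @return Tibble with `gene`, `observed_stat`, `p_value`, `q_value`,
#'   `significant`.
#' @export
permutation_significance <- function(X, y, B = 100L,
                                     hp = stage_hyperparams(), seed = 1L,
                                     alpha = 0.005) {
  if (B < 19L) abort("`B` must be at least 19 (p-value resolution).")
  observed <- max_stage_importance(X, y, hp, derive_seed(seed, "real"))
  exceed <- integer(length(observed))
  for (b in seq_len(B)) {
    sub_seed <- derive_seed(seed, "perm", b)
    y_b <- withr::with_seed(sub_seed, sample(y))
    null_stat <- max_stage_importance(X, y_b, hp, sub_seed)
    exceed <- exceed + (null_stat >= observed)
  }
  p <- (1 + exceed) / (B + 1)
  q <- bh_fdr(p)
  tibble::tibble(gene = colnames(X), observed_stat = observed,
                 p_value = p, q_value = q, significant = q < alpha)
}

# SMOTE + train + attribute, returning each gene's stage-maximum mean
# absolute attribution (computed on the original samples of X).
max_stage_importance <- function(X, y, hp, seed) {
  bal <- smote_balance(X, y, seed = seed)
  hp$seed <- seed
  model <- train_classifier(bal$X, bal$y, hp)
  att <- compute_attributions(model, X)
  stats <- vapply(0:2, function(s) mean_abs_importance(att, s)$importance,
                  numeric(ncol(X)))
  apply(matrix(stats, ncol = 3L), 1L, max)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false-discovery-rate adjustment: p-values sorted ascending,
#' `q_(i) = min over j >= i of p_(j) * m / j`, capped at 1, mapped back to
#' the input order. Inputs outside `(0, 1]` are an error.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  p.adjust(p_values, method = "BH")
}
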