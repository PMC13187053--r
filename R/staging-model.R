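#' Map a Braak score to the three-class stage label
#'
#' Braak 0-II -> 0 (Early), III-IV -> 1 (Mid), V-VI -> 2 (Late). Missing
#' scores map to `NA` (the sample is excluded downstream); scores outside
#' 0-6 are an error.
#'
#' @param braak Integer vector of Braak scores (0-6 or `NA`).
#' @return Integer vector of stage labels in `{0, 1, 2}` (or `NA`).
#' @export
braak_to_stage <- function(braak) {
  braak <- as.integer(braak)
  bad <- !is.na(braak) & (braak < 0L | braak > 6L)
  if (any(bad)) {
    abort(sprintf("Braak scores outside [0, 6]: %s",
                  paste(unique(braak[bad]), collapse = ", ")))
  }
  out <- rep(NA_integer_, length(braak))
  out[!is.na(braak)] <- findInterval(braak[!is.na(braak)], c(0L, 3L, 5L)) - 1L
  out
}

#' Stage-model hyperparameters
#'
#' Defaults are the gradient-boosted-tree settings the pipeline uses for
#' the three-class staging model: 100 trees of depth 10 with a conservative
#' learning rate (0.005), row and column subsampling of 0.5, and L1/L2
#' regularization (0.1 / 0.5), under a soft-probability multiclass
#' objective. Training is single-threaded with a fixed seed by default so
#' fits are exactly reproducible; set `nthread > 1` only where bit-level
#' reproducibility is not required.
#'
#' @param n_estimators Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param learning_rate Shrinkage (eta), in (0, 1].
#' @param subsample Row subsampling per tree.
#' @param colsample_bytree Column subsampling per tree.
#' @param reg_alpha L1 regularization.
#' @param reg_lambda L2 regularization.
#' @param seed Seed for the booster's internal RNG.
#' @param nthread Threads used by xgboost (default 1, deterministic).
#' @return A `stage_hyperparams` list.
#' @export
stage_hyperparams <- function(n_estimators = 100L, max_depth = 10L,
                              learning_rate = 0.005, subsample = 0.5,
                              colsample_bytree = 0.5, reg_alpha = 0.1,
                              reg_lambda = 0.5, seed = 1L, nthread = 1L) {
  if (learning_rate <= 0 || learning_rate > 1) {
    abort("`learning_rate` must be in (0, 1].")
  }
  if (n_estimators < 1L || max_depth < 1L || subsample <= 0 ||
      colsample_bytree <= 0 || reg_alpha < 0 || reg_lambda < 0) {
    abort("Hyperparameters must be positive.")
  }
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, subsample = subsample,
                 colsample_bytree = colsample_bytree, reg_alpha = reg_alpha,
                 reg_lambda = reg_lambda, seed = as.integer(seed),
                 nthread = as.integer(nthread)),
            class = "stage_hyperparams")
}

#' Stratified train/test split
#'
#' Splits sample indices into a training and held-out test set, stratified
#' by class. Per-class training counts follow a largest-remainder policy so
#' the training set totals `round(train_frac * n)` while per-class counts
#' stay within one sample of `train_frac * n_class`.
#'
#' @param y Integer class labels.
#' @param train_frac Training fraction (default 0.7).
#' @param seed Seed for the within-class sampling.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(y, train_frac = 0.7, seed = 1L) {
  classes <- sort(unique(y))
  counts <- vapply(classes, function(cl) sum(y == cl), integer(1))
  if (any(counts < 2L)) {
    abort("Every class needs at least 2 samples to stratify.")
  }
  base <- floor(train_frac * counts)
  remainder <- train_frac * counts - base
  total <- round(train_frac * length(y))
  extra <- total - sum(base)
  take <- base
  if (extra > 0L) {
    order_by_rem <- order(remainder, counts, decreasing = TRUE)
    take[order_by_rem[seq_len(extra)]] <- take[order_by_rem[seq_len(extra)]] + 1L
  }
  train <- withr::with_seed(seed, {
    unlist(lapply(seq_along(classes), function(i) {
      idx <- which(y == classes[i])
      sample(idx, take[i])
    }))
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' SMOTE class balancing
#'
#' Brings every minority class up to the majority-class count by
#' interpolating between a randomly chosen minority sample and one of its
#' `k_neighbors` nearest same-class neighbors (Euclidean distance), with a
#' uniform interpolation weight. Original rows are preserved verbatim at
#' the front of the returned matrices; only the training data should ever
#' be passed here.
#'
#' @param X Numeric samples x genes matrix.
#' @param y Integer class labels, one per row of `X`.
#' @param k_neighbors Neighborhood size; clamped to `n_class - 1` for small
#'   classes. A class with a single sample is an error (nothing to
#'   interpolate).
#' @param seed Seed for the sampling.
#' @return List with balanced `X` and `y`.
#' @export
smote_balance <- function(X, y, k_neighbors = 5L, seed = 1L) {
  stopifnot(nrow(X) == length(y))
  classes <- sort(unique(y))
  counts <- vapply(classes, function(cl) sum(y == cl), integer(1))
  n_major <- max(counts)
  if (all(counts == n_major)) return(list(X = X, y = y))
  if (any(counts < 2L)) {
    abort("SMOTE needs at least 2 samples per class to interpolate.")
  }
  synth <- withr::with_seed(seed, {
    parts <- lapply(seq_along(classes), function(i) {
      need <- n_major - counts[i]
      if (need == 0L) return(NULL)
      idx <- which(y == classes[i])
      Xc <- X[idx, , drop = FALSE]
      k <- min(k_neighbors, counts[i] - 1L)
      d <- as.matrix(stats::dist(Xc))
      diag(d) <- Inf
      nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
      base_i <- sample.int(counts[i], need, replace = TRUE)
      nb_i <- vapply(base_i, function(b) nn[b, sample.int(k, 1L)], integer(1))
      gap <- runif(need)
      rows <- Xc[base_i, , drop = FALSE] +
        gap * (Xc[nb_i, , drop = FALSE] - Xc[base_i, , drop = FALSE])
      rownames(rows) <- sprintf("synth_%s_%d", classes[i], seq_len(need))
      list(rows = rows, y = rep(classes[i], need))
    })
    parts[!vapply(parts, is.null, logical(1))]
  })
  X_new <- do.call(rbind, c(list(X), lapply(synth, `[[`, "rows")))
  y_new <- c(y, unlist(lapply(synth, `[[`, "y")))
  list(X = X_new, y = y_new)
}

#' Train the three-class staging model
#'
#' Fits a gradient-boosted tree ensemble with a soft-probability
#' multiclass objective on standardized expression features. Deterministic
#' for a fixed seed under the default single-thread contract.
#'
#' @param X Numeric samples x genes matrix (standardized features).
#' @param y Integer stage labels in `{0, 1, 2}`; all three classes must be
#'   present.
#' @param hp A [stage_hyperparams()].
#' @return A `stage_model`: list with the fitted `booster`, `gene_ids`
#'   (the fit-time gene order), `classes`, and `hp`.
#' @export
train_classifier <- function(X, y, hp = stage_hyperparams()) {
  assert_expression_matrix(X, "X")
  if (length(unique(y)) < 3L) {
    abort("Training requires all three stage classes to be present.")
  }
  dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y),
                                 nthread = hp$nthread)
  params <- list(objective = "multi:softprob", num_class = 3L,
                 max_depth = hp$max_depth, eta = hp$learning_rate,
                 subsample = hp$subsample,
                 colsample_bytree = hp$colsample_bytree,
                 alpha = hp$reg_alpha, lambda = hp$reg_lambda,
                 nthread = hp$nthread, seed = hp$seed)
  booster <- xgboost::xgb.train(params, dtrain, nrounds = hp$n_estimators,
                                verbose = 0)
  structure(list(booster = booster, gene_ids = colnames(X),
                 classes = 0:2, hp = hp),
            class = "stage_model")
}

#' Predict stage probabilities, classes, or margins
#'
#' @param object A `stage_model`.
#' @param newdata Samples x genes matrix; its gene order must match the
#'   order used at fit time exactly.
#' @param type `"prob"` (default; rows sum to 1), `"class"`, or
#'   `"margin"` (pre-softmax log-odds scores).
#' @param ... Unused.
#' @return A matrix (prob/margin) or integer vector (class).
#' @export
predict.stage_model <- function(object, newdata,
                                type = c("prob", "class", "margin"), ...) {
  type <- match.arg(type)
  check_gene_order(object, newdata)
  d <- xgboost::xgb.DMatrix(newdata, nthread = object$hp$nthread)
  if (type == "margin") {
    return(predict(object$booster, d, outputmargin = TRUE))
  }
  p <- predict(object$booster, d)
  if (type == "class") max.col(p) - 1L else p
}

check_gene_order <- function(model, X) {
  if (!identical(colnames(X), model$gene_ids)) {
    abort("Gene order of `newdata` does not match the model's fit-time order.")
  }
  invisible(TRUE)
}

#' Evaluate a staging model on the held-out test set
#'
#' Computes overall accuracy, one-vs-rest macro-averaged ROC AUC, and
#' per-class plus macro F1 on test samples that SMOTE never touched. If a
#' class is absent from `y_test`, its AUC is undefined; the report carries
#' an explicit `missing_classes` flag and the macro AUC averages the
#' remaining classes.
#'
#' @param model A `stage_model`.
#' @param X_test,y_test Held-out features and labels.
#' @return A one-row `stage_performance` tibble: `accuracy`, `auc_macro`,
#'   `f1_class0/1/2`, `f1_macro`, `missing_classes`.
#' @export
evaluate <- function(model, X_test, y_test) {
  prob <- predict(model, X_test, type = "prob")
  pred <- max.col(prob) - 1L
  acc <- mean(pred == y_test)
  f1 <- vapply(0:2, function(cl) f1_score(y_test == cl, pred == cl),
               numeric(1))
  present <- 0:2 %in% unique(y_test)
  aucs <- rep(NA_real_, 3L)
  for (cl in which(present)) {
    resp <- as.integer(y_test == (cl - 1L))
    if (length(unique(resp)) == 2L) {
      aucs[cl] <- as.numeric(pROC::auc(
        pROC::roc(resp, prob[, cl], quiet = TRUE, direction = "<",
                  levels = c(0, 1))))
    }
  }
  missing <- paste(which(!present | is.na(aucs)) - 1L, collapse = ",")
  out <- tibble::tibble(
    accuracy = acc,
    auc_macro = mean(aucs, na.rm = TRUE),
    f1_class0 = f1[1L], f1_class1 = f1[2L], f1_class2 = f1[3L],
    f1_macro = mean(f1),
    missing_classes = missing)
  class(out) <- c("stage_performance", class(out))
  out
}

# Per-class F1; 0 when precision/recall are undefined (no predictions or
# no true samples of the class).
f1_score <- function(truth, pred) {
  tp <- sum(truth & pred)
  if (tp == 0) return(0)
  prec <- tp / sum(pred)
  rec <- tp / sum(truth)
  2 * prec * rec / (prec + rec)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a staging model's native split-gain importances
#'
#' Returns the booster's own gain/cover/frequency feature importances (a
#' global ranking from the tree structure, distinct from the Shapley
#' attributions produced by [compute_attributions()]).
#'
#' @param x A `stage_model`.
#' @param ... Unused.
#' @return A tibble with `gene`, `gain`, `cover`, `frequency`.
#' @method tidy stage_model
#' @export
tidy.stage_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  tibble::tibble(gene = imp$Feature, gain = imp$Gain,
                 cover = imp$Cover, frequency = imp$Frequency)
}

#' One-row summary of a staging model
#'
#' @param x A `stage_model`.
#' @param ... Unused.
#' @return A one-row tibble with the fit dimensions and key
#'   hyperparameters.
#' @method glance stage_model
#' @export
glance.stage_model <- function(x, ...) {
  tibble::tibble(n_genes = length(x$gene_ids), n_classes = 3L,
                 n_estimators = x$hp$n_estimators,
                 max_depth = x$hp$max_depth,
                 learning_rate = x$hp$learning_rate)
}
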