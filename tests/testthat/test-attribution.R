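test_that("attributions satisfy local accuracy against the model margins", {
  d <- separable_xy(n_per_class = 15L, p = 8L)
  model <- train_classifier(d$X, d$y, fast_hp())
  att <- compute_attributions(model, d$X)
  marg <- predict(model, d$X, type = "margin")
  recon <- apply(att$values, c(1, 3), sum) +
    matrix(att$base_values, nrow(d$X), 3, byrow = TRUE)
  expect_lt(max(abs(recon - marg)), 1e-4)
  expect_error(compute_attributions(model, d$X[, rev(colnames(d$X))]),
               "Gene order")
})

test_that("attributions match exhaustive-subset Shapley values on small models", {
  set.seed(31)
  n <- 50
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:4)))
  y <- sample(0:2, n, replace = TRUE)
  model <- train_classifier(X, y, stage_hyperparams(
    n_estimators = 15L, max_depth = 4L, learning_rate = 0.3, seed = 5L))
  att <- compute_attributions(model, X)
  bf <- brute_force_shap(model, X)
  expect_lt(max(abs(aperm(att$values, c(1, 3, 2)) - bf[, , 1:4])), 1e-6)
  expect_lt(max(abs(att$base_values - bf[1, , 5])), 1e-6)
})

test_that("a single-feature signal concentrates attribution on that gene", {
  set.seed(6)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(paste0("s", 1:n), c("sig", "n1", "n2")))
  y <- ifelse(X[, "sig"] > 0.5, 2L, ifelse(X[, "sig"] > -0.5, 1L, 0L))
  X[, "n2"] <- 1 # constant feature
  model <- train_classifier(X, y, stage_hyperparams(
    n_estimators = 40L, max_depth = 2L, learning_rate = 0.3,
    subsample = 1, colsample_bytree = 1, seed = 2L))
  att <- compute_attributions(model, X)
  imp <- vapply(0:2, function(s) mean_abs_importance(att, s)$importance,
                numeric(3))
  rownames(imp) <- colnames(X)
  expect_true(all(imp["sig", ] > 10 * imp["n1", ]))
  expect_equal(unname(imp["n2", ]), rep(0, 3)) # constant gene: zero everywhere
})

test_that("duplicated identical features share importance symmetrically", {
  # Two identical copies of the signal feature; per-tree column subsampling
  # of 0.5 makes the booster use each copy in about half of its trees, so
  # mean-|attribution| importance should be split roughly evenly.
  set.seed(8)
  n <- 80
  base_feat <- rnorm(n)
  X <- cbind(a = base_feat, b = base_feat)
  rownames(X) <- paste0("s", 1:n)
  y <- ifelse(base_feat > 0.4, 2L, ifelse(base_feat > -0.4, 1L, 0L))
  model <- train_classifier(X, y, stage_hyperparams(
    n_estimators = 200L, max_depth = 3L, learning_rate = 0.1,
    subsample = 1, colsample_bytree = 0.5, seed = 3L))
  att <- compute_attributions(model, X)
  iv <- mean_abs_importance(att, 2)
  imp <- setNames(iv$importance, iv$gene)
  expect_lt(abs(imp[["a"]] - imp[["b"]]), 0.3 * max(imp))
})

test_that("mean absolute importance follows its definition and ignores sample order", {
  d <- separable_xy(n_per_class = 10L, p = 5L)
  model <- train_classifier(d$X, d$y, fast_hp())
  att <- compute_attributions(model, d$X)
  iv_all <- mean_abs_importance(att, 1)
  manual <- colMeans(abs(att$values[, , 2]))
  expect_equal(iv_all$importance, unname(manual))

  shuffled <- sample(att$sample_ids)
  iv_shuf <- mean_abs_importance(att, 1, samples = shuffled)
  expect_equal(iv_shuf$importance, iv_all$importance)
  expect_error(mean_abs_importance(att, 1, samples = character(0)), "empty")

  # hand arithmetic on the definition itself
  fake <- att
  fake$values[, 1, 1] <- c(0.5, 0.5, 2.0, rep(0, nrow(d$X) - 3))
  expect_equal(mean_abs_importance(fake, 0,
                                   samples = att$sample_ids[1:3])$importance[1],
               1.0)
})

test_that("top-k ordering is stable with lexicographic tie-breaks", {
  iv <- tibble::tibble(gene = c("a", "b", "c"), importance = c(3, 1, 2))
  expect_identical(top_k_genes(iv, 2), c("a", "c"))
  tie <- tibble::tibble(gene = c("b", "a"), importance = c(1, 1))
  expect_identical(top_k_genes(tie, 1), "a")
  expect_identical(top_k_genes(iv, 20), c("a", "c", "b"))
  expect_error(top_k_genes(iv, 0), ">= 1")
})

test_that("high-importance selection honors both rules and the scale contract", {
  iv <- tibble::tibble(gene = c("a", "b", "c"), importance = c(1, 0.9, 0.5))
  attr(iv, "scale") <- "minmax"
  expect_identical(select_high_importance(iv), c("a", "b"))

  eq <- tibble::tibble(gene = letters[1:10], importance = rep(0.5, 10))
  attr(eq, "scale") <- "minmax"
  expect_length(select_high_importance(eq, "percentile"), 0L)

  empty <- tibble::tibble(gene = character(0), importance = numeric(0))
  attr(empty, "scale") <- "minmax"
  expect_length(select_high_importance(empty), 0L)

  raw <- tibble::tibble(gene = "a", importance = 2)
  attr(raw, "scale") <- "raw"
  expect_error(select_high_importance(raw), "min-max")
})
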