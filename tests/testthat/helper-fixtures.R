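# Shared fixture builders. All data is generated in code at test time.

# A compact cohort configuration that keeps model fits fast while retaining
# every structural feature (planted genes, low-variance genes, duplicate
# IDs, pathway block).
small_config <- function(regions = "Hipp", n_genes = 60L, n_planted = 4L,
                         effect_size = 3, seed = 42L, ...) {
  synthetic_config(regions = regions, n_genes = n_genes,
                   n_planted = n_planted, effect_size = effect_size,
                   seed = seed, ...)
}

# Fast hyperparameters for tests that only need a working fitted model.
fast_hp <- function(n_estimators = 30L, seed = 1L, ...) {
  stage_hyperparams(n_estimators = n_estimators, seed = seed, ...)
}

# One aligned region dataset (preprocessed X plus labels) from a cohort.
aligned_region <- function(cohort, region = names(cohort$expression)[1L],
                           pre = preprocess_config()) {
  prep <- run_preprocessing(cohort$expression[[region]], pre)
  rd <- align_region(prep$matrix, cohort$clinical,
                     cohort$sample_maps[[region]])
  list(X = rd$expression, y = unname(rd$labels), qc = prep$qc)
}

# A tiny deterministic matrix with named dimensions for unit tests.
toy_matrix <- function(values, n_samples, gene_ids,
                       sample_ids = paste0("s", seq_len(n_samples))) {
  matrix(values, nrow = n_samples,
         dimnames = list(sample_ids, gene_ids))
}

# A separable 3-class feature matrix: `n_signal` informative features with
# class-specific means, the rest noise.
separable_xy <- function(n_per_class = 20L, p = 10L, n_signal = 3L,
                         shift = 3, seed = 7L) {
  withr::with_seed(seed, {
    n <- 3L * n_per_class
    y <- rep(0:2, each = n_per_class)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", 1:n), paste0("g", 1:p)))
    for (j in seq_len(n_signal)) {
      X[, j] <- X[, j] + shift * (y == (j - 1L) %% 3L)
    }
    list(X = X, y = y)
  })
}
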