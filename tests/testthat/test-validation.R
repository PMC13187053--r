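test_that("min-max normalization handles ranges, constants and idempotence", {
  iv <- tibble::tibble(gene = c("a", "b", "c"), importance = c(2, 4, 6))
  expect_equal(minmax_normalize(iv)$importance, c(0, 0.5, 1))
  con <- tibble::tibble(gene = c("a", "b"), importance = c(5, 5))
  expect_equal(minmax_normalize(con)$importance, c(0, 0))
  unit <- tibble::tibble(gene = c("a", "b", "c"), importance = c(0, 0.3, 1))
  expect_equal(minmax_normalize(unit)$importance, unit$importance)
  expect_identical(attr(minmax_normalize(iv), "scale"), "minmax")
})

test_that("the composite validation score is the 0.4/0.3/0.3 weighted sum", {
  expect_equal(validation_score(1, 1, 1), 1)
  expect_equal(validation_score(0, 0, 0), 0)
  expect_equal(validation_score(0.5, 0.5, 1.0), 0.65)
  expect_error(validation_score(1.2, 0, 0), "\\[0, 1\\]")

  # strict monotonicity in each argument
  base_score <- validation_score(0.5, 0.5, 0.5)
  expect_gt(validation_score(0.6, 0.5, 0.5), base_score)
  expect_gt(validation_score(0.5, 0.6, 0.5), base_score)
  expect_gt(validation_score(0.5, 0.5, 0.6), base_score)
})

test_that("confidence tiers reproduce the threshold rules", {
  dist <- seq(0, 1, length.out = 101) # percentile p sits at value p/100
  # stability 0.8, importance at the 80th percentile -> High
  expect_identical(as.character(assign_confidence(0.8, 0.80, dist)), "High")
  # stability 0.6, importance just above the median (60th pct) -> Medium
  expect_identical(as.character(assign_confidence(0.6, 0.60, dist)), "Medium")
  # stability 0.4, importance below the median -> Low
  expect_identical(as.character(assign_confidence(0.4, 0.10, dist)), "Low")
  # stability 0.2 -> Excluded
  expect_identical(as.character(assign_confidence(0.2, 0.99, dist)), "Excluded")
  expect_error(assign_confidence(0.5, 0.5, numeric(0)), "non-empty")

  # monotone: raising stability or importance never lowers the tier
  tiers <- c(High = 4L, Medium = 3L, Low = 2L, Excluded = 1L)
  grid <- expand.grid(st = c(0.2, 0.4, 0.6, 0.8, 1),
                      im = c(0.1, 0.45, 0.55, 0.8, 0.99))
  rank_of <- function(st, im) tiers[[as.character(assign_confidence(st, im, dist))]]
  for (i in seq_len(nrow(grid))) {
    r0 <- rank_of(grid$st[i], grid$im[i])
    expect_gte(rank_of(min(grid$st[i] + 0.2, 1), grid$im[i]), r0)
    expect_gte(rank_of(grid$st[i], min(grid$im[i] + 0.2, 1)), r0)
  }
})

test_that("BH correction matches the exhaustive step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")

  # all inputs of length <= 6 over a grid of p-values
  grid_p <- c(0.001, 0.01, 0.049, 0.2, 0.5, 1)
  withr::with_seed(99, {
    for (len in 1:6) {
      for (rep in 1:20) {
        p <- sample(grid_p, len, replace = TRUE)
        expect_equal(bh_fdr(p), bh_oracle(p))
      }
    }
  })
})

test_that("cross-validation stability is an exact fold-count fraction", {
  coh <- generate_cohort(small_config(n_genes = 50L, n_planted = 3L,
                                      effect_size = 3, seed = 13L))
  reg <- aligned_region(coh)
  stab <- cv_stability(reg$X, reg$y, K = 5L, k_top = 10L,
                       hp = fast_hp(), seed = 3L)
  expect_setequal(unique(stab$stage), c("Early", "Mid", "Late"))
  # Eq-1 exactness: stability * K is an integer in [0, K]
  expect_true(all(abs(stab$stability * 5 - round(stab$stability * 5)) < 1e-12))
  expect_true(all(stab$stability >= 0 & stab$stability <= 1))
  # genes never in a top list have stability 0 and no mean rank
  never <- stab[stab$stability == 0, ]
  expect_true(all(is.nan(never$mean_rank) | is.na(never$mean_rank)))

  # a strongly planted gene is recovered in every fold of its stage
  gt <- coh$ground_truth$planted
  hits <- dplyr::inner_join(gt, stab, by = c("gene", "stage"))
  expect_gte(mean(hits$stability == 1), 0.5)
  expect_true(all(dplyr::group_by(stab, stage) |>
                    dplyr::summarise(n = dplyr::n()) |>
                    dplyr::pull(n) == ncol(reg$X)))
})

test_that("cv_stability refuses classes too small for the fold count", {
  d <- separable_xy(n_per_class = 3L)
  expect_error(cv_stability(d$X, d$y, K = 5L, hp = fast_hp()), ">= 5")
})

test_that("gene_confidence assembles all evidence layers consistently", {
  coh <- generate_cohort(small_config(n_genes = 50L, n_planted = 3L,
                                      effect_size = 3, seed = 17L))
  reg <- aligned_region(coh)
  gc <- gene_confidence(reg$X, reg$y, hp = fast_hp(), seed = 7L)
  expect_equal(nrow(gc), ncol(reg$X) * 3L)
  expect_true(all(gc$train_norm >= 0 & gc$train_norm <= 1))
  expect_true(all(gc$test_norm >= 0 & gc$test_norm <= 1))
  expect_equal(gc$validation_score,
               0.4 * gc$train_norm + 0.3 * gc$test_norm + 0.3 * gc$stability)
  expect_true(all(gc$confidence %in% c("High", "Medium", "Low", "Excluded")))
  perf <- attr(gc, "performance")
  expect_s3_class(perf, "stage_performance")

  # tiers are consistent with the threshold table within each stage
  for (st in unique(gc$stage)) {
    sub <- gc[gc$stage == st, ]
    q75 <- quantile(sub$test_importance_raw, 0.75, names = FALSE)
    high <- sub$confidence == "High"
    expect_true(all(sub$stability[high] >= 0.8))
    expect_true(all(sub$test_importance_raw[high] > q75))
  }
})

test_that("permutation p-values are valid and detect planted signal rank", {
  coh <- generate_cohort(small_config(n_genes = 40L, n_planted = 3L,
                                      effect_size = 3, seed = 23L,
                                      frac_low_variance = 0))
  reg <- aligned_region(coh)
  res <- permutation_significance(reg$X, reg$y, B = 19L, hp = fast_hp(),
                                  seed = 5L)
  expect_equal(nrow(res), ncol(reg$X))
  expect_true(all(res$p_value >= 1 / 20 & res$p_value <= 1))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  # planted genes get the smallest possible p under this B
  gt_genes <- unique(coh$ground_truth$planted$gene)
  gt_genes <- intersect(gt_genes, res$gene)
  expect_gte(mean(res$p_value[res$gene %in% gt_genes] == 1 / 20), 0.5)
  expect_error(permutation_significance(reg$X, reg$y, B = 10L), "at least 19")

  # determinism
  res2 <- permutation_significance(reg$X, reg$y, B = 19L, hp = fast_hp(),
                                   seed = 5L)
  expect_identical(res, res2)
})
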