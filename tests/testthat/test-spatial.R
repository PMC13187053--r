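test_that("row normalization scales each gene by its regional maximum", {
  m <- matrix(c(0, 2, 4, 0, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("r1", "r2", "r3")))
  rn <- row_normalize(m)
  expect_equal(unname(rn["g1", ]), c(0, 0.5, 1))
  expect_equal(unname(rn["g2", ]), c(0, 0, 0))
  # every nonzero row attains exactly 1
  set.seed(2)
  m2 <- matrix(rlnorm(30), 6, 5, dimnames = list(paste0("g", 1:6), paste0("r", 1:5)))
  expect_equal(unname(apply(row_normalize(m2), 1, max)), rep(1, 6))
  expect_error(row_normalize(matrix(c(-1, 2), 1)), "non-negative")
})

test_that("stage profiles are min-max across regions and scale-invariant", {
  m <- matrix(c(0.1, 0.3, 0.5, 0.3, 0.5, 0.7), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("r1", "r2", "r3")))
  attr(m, "state") <- "row_normalized"
  pr <- stage_region_profile(m)
  expect_equal(pr$profile, c(0, 0.5, 1))

  cons <- matrix(0.5, 2, 3, dimnames = list(c("g1", "g2"), c("r1", "r2", "r3")))
  attr(cons, "state") <- "row_normalized"
  expect_warning(pc <- stage_region_profile(cons), "Constant")
  expect_equal(pc$profile, c(0, 0, 0))

  single <- matrix(c(0, 1, 0, 0, 1, 0), 2, 3, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("r1", "r2", "r3")))
  attr(single, "state") <- "row_normalized"
  expect_equal(stage_region_profile(single)$profile, c(0, 1, 0))

  one_col <- matrix(1, 2, 1, dimnames = list(c("g1", "g2"), "r1"))
  attr(one_col, "state") <- "row_normalized"
  expect_error(stage_region_profile(one_col), "2 regions")
  m_raw <- m
  attr(m_raw, "state") <- NULL
  expect_error(stage_region_profile(m_raw), "row-normalized")

  # scale invariance through the composed operator: scaling any raw gene
  # row by a positive constant leaves the profile unchanged
  set.seed(5)
  raw <- matrix(rlnorm(20), 4, 5,
                dimnames = list(paste0("g", 1:4), paste0("r", 1:5)))
  p1 <- stage_region_profile(row_normalize(raw))
  raw2 <- raw
  raw2[2, ] <- raw2[2, ] * 37
  p2 <- stage_region_profile(row_normalize(raw2))
  expect_equal(p1, p2)
})

test_that("cross-stage overlap reproduces the shared-gene arithmetic", {
  lists <- list(Early = paste0("e", 1:20), Mid = paste0("m", 1:20),
                Late = paste0("l", 1:20))
  ov <- cross_stage_overlap(lists)
  expect_equal(ov$n_selected, 60L)
  expect_equal(ov$n_unique, 60L)
  expect_equal(ov$overlap_fraction, 0)

  # exactly one gene shared by two stages: 1/60
  lists$Mid[1] <- "e1"
  ov1 <- cross_stage_overlap(lists)
  expect_equal(ov1$n_unique, 59L)
  expect_equal(ov1$n_multi_stage, 1L)
  expect_equal(ov1$overlap_fraction, 1 / 60)
  shared <- ov1$pairwise[ov1$pairwise$stage_a == "Early" &
                           ov1$pairwise$stage_b == "Mid", ]
  expect_identical(shared$shared, "e1")

  same <- replicate(3, paste0("g", 1:20), simplify = FALSE)
  names(same) <- c("Early", "Mid", "Late")
  ov3 <- cross_stage_overlap(same)
  expect_equal(ov3$n_unique, 20L)
  expect_equal(ov3$n_multi_stage, 20L)
  expect_equal(ov3$overlap_fraction, 20 / 60)

  bad <- list(Early = c("a", "a"), Mid = c("b", "c"))
  expect_error(cross_stage_overlap(bad), "Duplicate")
})

test_that("heatmap tables sort genes and regions by overall importance", {
  iv <- function(genes, imps) {
    out <- tibble::tibble(gene = genes, importance = imps)
    attr(out, "scale") <- "raw"
    out
  }
  one <- list(r1 = iv(c("a", "b", "c"), c(3, 1, 2)))
  hm <- heatmap_table(one, k = 3)
  expect_identical(rownames(hm), c("a", "c", "b"))
  expect_equal(unname(hm[, "r1"]), c(1, 0.5, 0))

  # a gene absent from one region appears with a 0 cell; the region with
  # the largest summed importance comes first
  two <- list(weak = iv(c("a", "b"), c(1, 0.2)),
              strong = iv(c("a", "c"), c(5, 4)))
  hm2 <- heatmap_table(two, k = 3)
  expect_identical(colnames(hm2)[1], "strong")
  expect_equal(hm2["c", "weak"], 0)
  expect_true(all(hm2 >= 0 & hm2 <= 1))
})

test_that("Spearman rho matches the rank-formula oracle for small n", {
  withr::with_seed(10, {
    for (rep in 1:20) {
      n <- sample(4:8, 1)
      x <- rnorm(n); y <- rnorm(n)
      got <- suppressWarnings(cor(x, y, method = "spearman"))
      expect_equal(got, spearman_oracle(x, y), tolerance = 1e-12)
    }
  })
})

test_that("co-expression summaries follow the overlap and significance rules", {
  n <- 60
  withr::with_seed(3, {
    biom <- rnorm(n)
    noise <- matrix(rnorm(n * 3), n, 3)
  })
  expr <- cbind(bm = exp(biom), mono = exp(2 * biom), noise)
  colnames(expr) <- c("bm", "mono", "n1", "n2", "n3")
  rownames(expr) <- paste0("s", 1:n)
  attr(expr, "region") <- "Hipp"

  # perfectly monotone pair: rho = 1
  res <- coexpression_summary(expr, "bm", pathway_panel("p", c("mono")),
                              details = TRUE)
  expect_equal(res$pairs$rho, 1)
  expect_equal(res$summary$n_tested, 1L)
  expect_equal(res$summary$n_significant, 1L)

  # independent noise genes: ~binomial(3, 0.05) significant
  res2 <- coexpression_summary(expr, "bm",
                               pathway_panel("noise", c("n1", "n2", "n3")))
  expect_lte(res2$n_significant, 1L)
  expect_equal(res2$n_tested, 3L)
  expect_identical(res2$region, "Hipp")

  # panel genes missing from the matrix reduce n_tested; biomarker itself
  # is never tested against itself
  res3 <- coexpression_summary(expr, "bm",
                               pathway_panel("mix", c("bm", "mono", "zz")))
  expect_equal(res3$n_tested, 1L)

  expect_error(coexpression_summary(expr, "absent", pathway_panel("p", "mono")),
               "absent")
})

test_that("pairs with too few overlapping samples are skipped", {
  expr <- cbind(bm = c(1, 2, 3, 4, NA, NA),
                few = c(2, 4, 6, NA, 1, 1),
                ok = c(5, 3, 1, 2, 4, 6))
  rownames(expr) <- paste0("s", 1:6)
  res <- coexpression_summary(expr, "bm", pathway_panel("p", c("few", "ok")),
                              min_overlap = 4L)
  expect_equal(res$n_tested, 1L) # "few" has only 3 overlapping samples
})

test_that("planted pathway blocks are recovered by co-expression analysis", {
  coh <- generate_cohort(synthetic_config(
    regions = "Hipp", n_genes = 80L, n_planted = 0L,
    pathway_block_size = 6L, pathway_block_cor = 0.6, seed = 19L))
  prep <- run_preprocessing(coh$expression$Hipp)
  blocks <- coh$ground_truth$pathway_blocks
  panel <- pathway_panel("synthetic_block", unique(blocks$gene))
  res <- coexpression_summary(prep$matrix, blocks$biomarker[1], panel)
  expect_gte(res$n_significant / res$n_tested, 0.8)
  expect_gt(res$mean_abs_rho, 0.3)
})
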