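#' Run the full staging and biomarker-validation pipeline
#'
#' Executes, for every region of a cohort: preprocessing, stage labeling,
#' stratified split, SMOTE balancing, model training and evaluation,
#' Shapley attribution, the gene-confidence framework, and (optionally)
#' permutation significance with FDR correction. Afterwards it aggregates
#' across regions: per-stage heatmap tables, regional importance profiles,
#' the cross-stage overlap statistic, and pathway co-expression checks.
#' A failure in one region is recorded and the remaining regions proceed.
#' Fully deterministic for a fixed `seed` (single-threaded training).
#'
#' @param cohort A `synthetic_cohort`, or any list with `expression`
#'   (named list of samples x genes matrices), `clinical` (tibble) and
#'   `sample_maps` (named list of sample -> subject vectors).
#' @param hp A [stage_hyperparams()].
#' @param pre A [preprocess_config()].
#' @param K,k_top Stability parameters (defaults 5, 20).
#' @param B Label permutations for significance testing; `B = 0` skips the
#'   permutation stage, values in `(0, 19)` are refused.
#' @param perm_genes Number of genes (sampled deterministically) on which
#'   permutation testing runs; `NULL` tests all genes.
#' @param alpha FDR threshold for significance counts (default 0.005).
#' @param coexpr_tasks Optional tibble with columns `region`, `biomarker`,
#'   `panel` (list-column of [pathway_panel()] objects). When `NULL` and
#'   the cohort carries synthetic ground truth, tasks are derived from its
#'   planted pathway blocks.
#' @param seed Master seed; every region and stage derives sub-seeds.
#' @return A `stage_run_report`: list of tibbles and matrices (see
#'   [emit_reports()] for the on-disk layout).
#' @export
run_full_pipeline <- function(cohort, hp = stage_hyperparams(),
                              pre = preprocess_config(), K = 5L,
                              k_top = 20L, B = 0L, perm_genes = 200L,
                              alpha = 0.005, coexpr_tasks = NULL,
                              seed = 1L) {
  regions <- names(cohort$expression)
  if (length(regions) == 0L) abort("Cohort contains no regions.")
  if (B > 0L && B < 19L) abort("`B` must be 0 (skip) or at least 19.")

  qc <- list(); performance <- list(); confidence <- list()
  perm <- list(); errors <- list(); processed <- list(); labels <- list()
  for (region in regions) {
    res <- tryCatch({
      region_seed <- derive_seed(seed, "region", region)
      prep <- run_preprocessing(cohort$expression[[region]], pre)
      rd <- align_region(prep$matrix, cohort$clinical,
                         cohort$sample_maps[[region]])
      X <- rd$expression
      y <- unname(rd$labels)
      gc <- gene_confidence(X, y, hp = hp, K = K, k_top = k_top,
                            seed = region_seed)
      perf <- attr(gc, "performance")
      attr(gc, "model") <- NULL
      attr(gc, "performance") <- NULL
      pm <- NULL
      if (B >= 19L) {
        Xp <- X
        if (!is.null(perm_genes) && ncol(X) > perm_genes) {
          keep <- withr::with_seed(derive_seed(region_seed, "permsub"),
                                   sort(sample.int(ncol(X), perm_genes)))
          Xp <- X[, keep, drop = FALSE]
        }
        pm <- permutation_significance(Xp, y, B = B, hp = hp,
                                       seed = derive_seed(region_seed, "perm"),
                                       alpha = alpha)
        pm <- dplyr::mutate(pm, region = region, .before = 1L)
      }
      list(qc = prep$qc,
           perf = dplyr::mutate(perf, region = region, .before = 1L),
           conf = dplyr::mutate(tibble::as_tibble(gc), region = region,
                                .before = 1L),
           perm = pm, X = X, y = y)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[region]] <- tibble::tibble(region = region,
                                         error = conditionMessage(res))
      next
    }
    qc[[region]] <- res$qc
    performance[[region]] <- res$perf
    confidence[[region]] <- res$conf
    perm[[region]] <- res$perm
    processed[[region]] <- res$X
    labels[[region]] <- res$y
  }
  confidence_tab <- dplyr::bind_rows(confidence)
  perm_tab <- if (length(perm)) dplyr::bind_rows(perm) else NULL

  tier_counts <- NULL; significant_counts <- NULL
  heatmaps <- list(); profiles <- NULL; overlap <- NULL
  regional_importance <- NULL
  if (nrow(confidence_tab) > 0L) {
    tier_counts <- confidence_tab |>
      dplyr::count(.data$region, .data$confidence, name = "n_genes") |>
      tidyr::complete(region = unique(confidence_tab$region),
                      confidence = factor(CONFIDENCE_LEVELS,
                                          levels = CONFIDENCE_LEVELS),
                      fill = list(n_genes = 0L))
    agg <- aggregate_importance(confidence_tab, k_top)
    heatmaps <- agg$heatmaps
    profiles <- agg$profiles
    regional_importance <- agg$regional_importance
    overlap <- agg$overlap
  }
  if (!is.null(perm_tab) && nrow(perm_tab) > 0L) {
    significant_counts <- perm_tab |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(n_tested = dplyr::n(),
                       n_significant = sum(.data$significant))
  }

  coexpression <- run_coexpression(cohort, processed, coexpr_tasks)

  report <- structure(
    list(performance = dplyr::bind_rows(performance),
         qc = dplyr::bind_rows(qc),
         confidence = confidence_tab,
         tier_counts = tier_counts,
         permutation = perm_tab,
         significant_counts = significant_counts,
         heatmaps = heatmaps,
         profiles = profiles,
         regional_importance = regional_importance,
         overlap = overlap,
         coexpression = coexpression,
         errors = dplyr::bind_rows(errors),
         provenance = list(seed = seed,
                           config_hash = rlang::hash(list(hp, pre, K, k_top,
                                                          B, perm_genes,
                                                          alpha, seed)),
                           package_version =
                             as.character(utils::packageVersion("stagemarker")))),
    class = "stage_run_report")
  report$provenance$result_hash <- rlang::hash(report[c(
    "performance", "qc", "confidence", "tier_counts", "permutation",
    "significant_counts", "profiles", "overlap")])
  report
}

# Per-stage regional aggregation from the pooled confidence table: heatmap
# tables, row-normalized regional profiles, and the cross-stage overlap of
# the per-stage top-k lists (ranked by summed training importance).
aggregate_importance <- function(confidence_tab, k_top) {
  heatmaps <- list(); prof <- list(); top_lists <- list(); regional <- list()
  for (stage in STAGE_LEVELS) {
    sub <- dplyr::filter(confidence_tab, .data$stage == !!stage)
    by_region <- split(sub, sub$region)
    ivs <- lapply(by_region, function(d) {
      iv <- tibble::tibble(gene = d$gene, importance = d$train_importance_raw)
      attr(iv, "scale") <- "raw"
      iv
    })
    heatmaps[[stage]] <- heatmap_table(ivs, k = k_top)
    raw <- gene_region_matrix(ivs)
    nz <- raw[rowSums(raw) > 0, , drop = FALSE]
    if (nrow(nz) > 0L && ncol(nz) >= 2L) {
      rn <- row_normalize(nz)
      pr <- stage_region_profile(rn)
      pr$stage <- stage
      prof[[stage]] <- pr
      # Row-normalized cells plus raw-scale per-gene summaries (the raw
      # mean/SD live on a different scale than the normalized cells, so
      # they are carried as separate columns, never derived from them).
      regional[[stage]] <- tibble::as_tibble(rn, rownames = "gene") |>
        dplyr::mutate(stage = stage,
                      mean_importance = rowMeans(nz),
                      std_importance = apply(nz, 1L, sd),
                      .after = "gene")
    }
    pooled <- tibble::tibble(gene = rownames(raw), importance = rowSums(raw))
    top_lists[[stage]] <- top_k_genes(pooled, k_top)
  }
  list(heatmaps = heatmaps,
       profiles = if (length(prof)) dplyr::bind_rows(prof) else NULL,
       regional_importance = if (length(regional)) dplyr::bind_rows(regional) else NULL,
       overlap = cross_stage_overlap(top_lists))
}

# Resolve co-expression tasks (explicit or derived from synthetic ground
# truth) against the preprocessed matrices.
run_coexpression <- function(cohort, processed, coexpr_tasks) {
  if (is.null(coexpr_tasks)) {
    gt <- cohort$ground_truth
    if (is.null(gt) || is.null(gt$pathway_blocks) ||
        nrow(gt$pathway_blocks) == 0L) {
      return(NULL)
    }
    coexpr_tasks <- gt$pathway_blocks |>
      dplyr::group_by(.data$region, .data$panel, .data$biomarker) |>
      dplyr::summarise(genes = list(.data$gene), .groups = "drop") |>
      dplyr::mutate(panel_obj = purrr::map2(.data$panel, .data$genes,
                                            pathway_panel)) |>
      dplyr::select("region", biomarker = "biomarker", panel = "panel_obj")
  }
  purrr::pmap_dfr(coexpr_tasks, function(region, biomarker, panel, ...) {
    expr <- processed[[region]]
    if (is.null(expr) || !biomarker %in% colnames(expr)) {
      return(NULL)
    }
    coexpression_summary(expr, biomarker, panel)
  })
}

#' @export
print.stage_run_report <- function(x, ...) {
  cat(sprintf("<stage_run_report> %d region(s), seed %s\n",
              nrow(x$performance), x$provenance$seed))
  if (!is.null(x$performance) && nrow(x$performance)) {
    print(x$performance)
  }
  if (nrow(x$errors)) {
    cat("Regions with errors:", paste(x$errors$region, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits the analysis tables as CSV and the overlap/provenance summaries
#' as JSON: `performance.csv`, `qc.csv`, `gene_confidence.csv`,
#' `tier_counts.csv`, `significant_counts.csv` and `permutation.csv`
#' (when permutation ran), `radar_profile.csv`, `heatmap_<stage>.csv`,
#' `coexpression.csv`, `overlap.json`, and `summary.json`.
#'
#' @param report A `stage_run_report`.
#' @param outdir Output directory (created if possible; unwritable
#'   locations are an error).
#' @return `outdir`, invisibly.
#' @export
emit_reports <- function(report, outdir) {
  stopifnot(inherits(report, "stage_run_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir) || file.access(outdir, 2L) != 0L) {
    abort(sprintf("Output directory is not writable: %s", outdir))
  }
  w <- function(x, name) {
    if (!is.null(x) && nrow(x) > 0L) {
      readr::write_csv(x, file.path(outdir, name))
    }
  }
  w(report$performance, "performance.csv")
  w(report$qc, "qc.csv")
  w(report$confidence, "gene_confidence.csv")
  w(report$tier_counts, "tier_counts.csv")
  w(report$permutation, "permutation.csv")
  w(report$significant_counts, "significant_counts.csv")
  w(report$profiles, "radar_profile.csv")
  w(report$regional_importance, "regional_importance.csv")
  w(report$coexpression, "coexpression.csv")
  for (stage in names(report$heatmaps)) {
    hm <- report$heatmaps[[stage]]
    tab <- tibble::as_tibble(hm, rownames = "gene")
    readr::write_csv(tab, file.path(outdir,
                                    sprintf("heatmap_%s.csv", tolower(stage))))
  }
  if (!is.null(report$overlap)) {
    ov <- report$overlap
    ov$pairwise <- NULL
    ov$pairwise_shared <- report$overlap$pairwise
    jsonlite::write_json(ov, file.path(outdir, "overlap.json"),
                         auto_unbox = TRUE, dataframe = "rows")
  }
  jsonlite::write_json(report$provenance, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE)
  invisible(outdir)
}
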