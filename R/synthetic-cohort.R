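#' Configuration for the synthetic multi-region cohort generator
#'
#' The defaults emulate the structure of the Mount Sinai Brain Bank cohort
#' the pipeline was designed for: 33/40/51 subjects in the Early/Mid/Late
#' Braak stage groups, eleven brain regions, and a desk-scale gene universe
#' of 2,000 genes per region (the real cohort measures ~36,000). Planted,
#' stage- and region-specific differential genes carry the recoverable
#' signal; low-variance genes, duplicate ENTREZ identifiers, and one
#' latent-factor-correlated pathway block per region reproduce the data
#' features the preprocessing and co-expression stages must handle.
#'
#' @param n_per_stage Named integer vector of subjects per stage group
#'   (`early`, `mid`, `late`).
#' @param regions Character vector of region labels.
#' @param n_genes Genes per region (desk scale default 2000).
#' @param n_genes_override Optional named vector of per-region gene-count
#'   overrides (the full-scale cohort gives the amygdala a larger universe).
#' @param n_planted Planted differential genes per (stage, region); the
#'   three per-stage sets are disjoint within a region.
#' @param effect_size Mean shift of a planted gene in its stage, in units
#'   of the gene's standard deviation. Must be non-negative.
#' @param frac_low_variance Fraction of genes generated with variance below
#'   the 0.1 filtering threshold.
#' @param frac_duplicate_ids Fraction of genes sharing an ENTREZ ID with
#'   another gene (values remain distinct, so aggregation is non-trivial).
#' @param noise_family Baseline expression noise: `"lognormal"` (default;
#'   positive, heavy-tailed, heterogeneous variances) or
#'   `"negative_binomial"` for count-like data.
#' @param pathway_block_size Number of panel genes in the correlated
#'   pathway block planted per region (plus one biomarker gene).
#' @param pathway_block_cor Latent-factor correlation between the block's
#'   biomarker and each panel gene.
#' @param seed Master seed; all region- and stage-level randomness is
#'   sub-seeded from it, so adding a region never perturbs the others.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_stage = c(early = 33L, mid = 40L, late = 51L),
                             regions = MSBB_REGIONS,
                             n_genes = 2000L,
                             n_genes_override = NULL,
                             n_planted = 10L,
                             effect_size = 1.5,
                             frac_low_variance = 0.1,
                             frac_duplicate_ids = 0.05,
                             noise_family = c("lognormal", "negative_binomial"),
                             pathway_block_size = 6L,
                             pathway_block_cor = 0.6,
                             seed = 1L) {
  noise_family <- match.arg(noise_family)
  if (length(regions) < 1L) abort("At least one region is required.")
  if (effect_size < 0) abort("`effect_size` must be non-negative.")
  if (frac_low_variance < 0 || frac_low_variance >= 1 ||
      frac_duplicate_ids < 0 || frac_duplicate_ids >= 1) {
    abort("`frac_low_variance` and `frac_duplicate_ids` must be in [0, 1).")
  }
  n_per_stage <- as.integer(n_per_stage)
  names(n_per_stage) <- c("early", "mid", "late")
  cfg <- structure(
    list(n_per_stage = n_per_stage, regions = as.character(regions),
         n_genes = as.integer(n_genes), n_genes_override = n_genes_override,
         n_planted = as.integer(n_planted), effect_size = effect_size,
         frac_low_variance = frac_low_variance,
         frac_duplicate_ids = frac_duplicate_ids,
         noise_family = noise_family,
         pathway_block_size = as.integer(pathway_block_size),
         pathway_block_cor = pathway_block_cor,
         seed = as.integer(seed)),
    class = "synthetic_config")
  for (r in cfg$regions) {
    ng <- region_n_genes(cfg, r)
    budget <- 3L * cfg$n_planted +
      ceiling(cfg$frac_low_variance * ng) +
      ceiling(cfg$frac_duplicate_ids * ng) +
      cfg$pathway_block_size + 1L
    if (budget > ng) {
      abort(sprintf(
        "Region %s: planted/low-variance/duplicate/pathway genes (%d) exceed n_genes (%d).",
        r, budget, ng))
    }
  }
  cfg
}

region_n_genes <- function(cfg, region) {
  if (!is.null(cfg$n_genes_override) && region %in% names(cfg$n_genes_override)) {
    as.integer(cfg$n_genes_override[[region]])
  } else {
    cfg$n_genes
  }
}

#' Generate a synthetic multi-region cohort
#'
#' Draws a clinical table (Braak score uniform within each stage group's
#' range, demographics matched to the emulated cohort's summary statistics)
#' and one expression matrix per region with planted stage-specific
#' differential genes, low-variance genes, duplicate gene IDs, and a
#' correlated pathway block. Deterministic for a fixed `seed`.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_cohort`: list with `expression` (named list of
#'   samples x genes matrices), `clinical` (tibble), `sample_maps` (named
#'   list of sample -> subject vectors), `ground_truth` (planted genes,
#'   pathway blocks, low-variance and duplicate injections), and `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n_stage <- config$n_per_stage
  n_sub <- sum(n_stage)
  stage_of_subject <- rep(0:2, times = n_stage)
  braak_range <- list(`0` = 0:2, `1` = 3:4, `2` = 5:6)

  clinical <- withr::with_seed(derive_seed(config$seed, "clinical"), {
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n_sub)),
      braak = vapply(stage_of_subject, function(s) {
        r <- braak_range[[as.character(s)]]
        r[sample.int(length(r), 1L)]
      }, integer(1)),
      age = round(rnorm(n_sub, 84.13, 7.23), 1),
      sex = sample(c("F", "M"), n_sub, replace = TRUE, prob = c(0.72, 0.28)),
      pmi = round(pmax(rnorm(n_sub, 361.02, 318.73), 10), 0),
      ph = round(rnorm(n_sub, 6.37, 0.28), 2)
    )
  })

  max_genes <- max(vapply(config$regions, function(r) region_n_genes(config, r),
                          integer(1)))
  # Shared ENTREZ-style universe so genes align across regions.
  universe <- withr::with_seed(derive_seed(config$seed, "universe"), {
    as.character(sort(sample.int(899999L, max_genes) + 100000L))
  })

  expression <- list()
  sample_maps <- list()
  planted <- list()
  blocks <- list()
  lowvar <- list()
  dups <- list()
  for (ri in seq_along(config$regions)) {
    region <- config$regions[ri]
    gen <- generate_region(config, region, universe, stage_of_subject,
                           clinical$subject_id)
    expression[[region]] <- gen$matrix
    sample_maps[[region]] <- gen$sample_map
    planted[[region]] <- gen$planted
    blocks[[region]] <- gen$block
    lowvar[[region]] <- gen$lowvar
    dups[[region]] <- gen$dups
  }

  ground_truth <- structure(
    list(planted = dplyr::bind_rows(planted),
         pathway_blocks = dplyr::bind_rows(blocks),
         low_variance = dplyr::bind_rows(lowvar),
         duplicates = dplyr::bind_rows(dups)),
    class = "cohort_ground_truth")

  structure(
    list(expression = expression, clinical = clinical,
         sample_maps = sample_maps, ground_truth = ground_truth,
         config = config),
    class = "synthetic_cohort")
}

# One region's matrix: lognormal (or NB) baseline, then role-specific
# overwrites for low-variance, pathway-block, and planted genes.
generate_region <- function(config, region, universe, stage_of_subject,
                            subject_ids) {
  ng <- region_n_genes(config, region)
  n <- length(stage_of_subject)
  gene_ids <- universe[seq_len(ng)]
  sample_ids <- paste(region, subject_ids, sep = "_")

  withr::with_seed(derive_seed(config$seed, "region", region), {
    meanlog <- runif(ng, 0.5, 2)
    sdlog <- runif(ng, 0.3, 0.8)
    m <- if (config$noise_family == "lognormal") {
      vapply(seq_len(ng), function(j) rlnorm(n, meanlog[j], sdlog[j]),
             numeric(n))
    } else {
      vapply(seq_len(ng), function(j)
        as.numeric(rnbinom(n, mu = exp(meanlog[j] + sdlog[j]^2 / 2), size = 2)),
        numeric(n))
    }
    dimnames(m) <- list(sample_ids, gene_ids)

    # Disjoint role assignment over gene indices.
    n_lowvar <- ceiling(config$frac_low_variance * ng)
    n_dup <- ceiling(config$frac_duplicate_ids * ng)
    n_block <- config$pathway_block_size + 1L
    roles <- sample.int(ng, 3L * config$n_planted + n_lowvar + n_dup + n_block)
    take <- function(k) {
      if (k == 0L) return(integer(0))
      out <- roles[seq_len(k)]
      roles <<- roles[-seq_len(k)]
      out
    }
    planted_idx <- lapply(0:2, function(s) take(config$n_planted))
    lowvar_idx <- take(n_lowvar)
    dup_idx <- take(n_dup)
    block_idx <- take(n_block)

    # Low-variance genes: near-constant, variance well below 0.1.
    for (j in lowvar_idx) {
      m[, j] <- runif(1, 1, 5) + rnorm(n, 0, 0.05)
    }

    # Pathway block: biomarker + panel genes share a latent factor, so
    # their pairwise Spearman correlation approximates pathway_block_cor.
    z <- rnorm(n)
    rho <- config$pathway_block_cor
    biomarker_j <- block_idx[1L]
    m[, biomarker_j] <- exp(meanlog[biomarker_j] + sdlog[biomarker_j] * z)
    for (j in block_idx[-1L]) {
      e <- rho * z + sqrt(1 - rho^2) * rnorm(n)
      m[, j] <- exp(meanlog[j] + sdlog[j] * e)
    }

    # Planted stage-specific genes: constant shift of effect_size SDs for
    # the samples of the target stage.
    planted_tab <- list()
    for (s in 0:2) {
      for (j in planted_idx[[s + 1L]]) {
        shift <- config$effect_size * sd_pop(m[, j])
        m[stage_of_subject == s, j] <- m[stage_of_subject == s, j] + shift
      }
      planted_tab[[s + 1L]] <- tibble::tibble(
        region = region, stage = STAGE_LEVELS[s + 1L],
        gene = gene_ids[planted_idx[[s + 1L]]],
        effect_size = config$effect_size)
    }

    # Duplicate-ID injection: gene takes another gene's ID; values differ.
    dup_tab <- NULL
    if (n_dup > 0L) {
      donors <- setdiff(seq_len(ng), dup_idx)
      donor_idx <- sample(donors, n_dup, replace = FALSE)
      cn <- colnames(m)
      cn[dup_idx] <- cn[donor_idx]
      colnames(m) <- cn
      dup_tab <- tibble::tibble(region = region, gene = cn[dup_idx])
    }

    region_of(m) <- region
    list(matrix = m,
         sample_map = setNames(subject_ids, sample_ids),
         planted = dplyr::bind_rows(planted_tab),
         block = tibble::tibble(
           region = region, panel = "synthetic_block",
           biomarker = gene_ids[biomarker_j],
           gene = gene_ids[block_idx[-1L]],
           target_cor = rho),
         lowvar = tibble::tibble(region = region, gene = gene_ids[lowvar_idx]),
         dups = dup_tab)
  })
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Generate a null cohort (no planted effects)
#'
#' Identical to [generate_cohort()] but with zero planted differential
#' genes, so stage labels are independent of expression. Used to check
#' false-discovery control of the permutation machinery.
#'
#' @param config A [synthetic_config()]; its `n_planted` is forced to 0.
#' @return A `synthetic_cohort` whose ground-truth planted table is empty.
#' @export
null_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  config$n_planted <- 0L
  generate_cohort(config)
}

#' Write a synthetic cohort to disk in the canonical formats
#'
#' Emits one TSV expression matrix per region, `clinical.csv`,
#' `sample_maps.csv`, and `ground_truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (region in names(cohort$expression)) {
    write_expression_matrix(cohort$expression[[region]],
                            file.path(dir, paste0(region, ".tsv")))
  }
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  maps <- purrr::imap_dfr(cohort$sample_maps, function(map, region) {
    tibble::tibble(region = region, sample_id = names(map),
                   subject_id = unname(map))
  })
  readr::write_csv(maps, file.path(dir, "sample_maps.csv"))
  jsonlite::write_json(cohort$ground_truth[!vapply(cohort$ground_truth, is.null, logical(1))],
                       file.path(dir, "ground_truth.json"), dataframe = "rows")
  invisible(dir)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d regions, %d subjects, seed %d\n",
              length(x$expression), nrow(x$clinical), x$config$seed))
  invisible(x)
}
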