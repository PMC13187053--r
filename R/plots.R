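#' Heatmap of top-gene importance across regions
#'
#' Tile plot of a [heatmap_table()] matrix: rows are genes (most important
#' at the top), columns regions, fill the within-region min-max-normalized
#' importance.
#'
#' @param hm Matrix from [heatmap_table()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_importance_heatmap <- function(hm, title = NULL) {
  df <- tibble::as_tibble(hm, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "region",
                        values_to = "importance") |>
    dplyr::mutate(gene = factor(.data$gene, levels = rev(rownames(hm))),
                  region = factor(.data$region, levels = colnames(hm)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$gene,
                                   fill = .data$importance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1),
                                  name = "Normalized\nimportance") +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' Radar-style plot of stage-level regional importance profiles
#'
#' Polar line plot of the per-stage regional profiles (column means of the
#' row-normalized importance matrix, min-max scaled across regions).
#'
#' @param profiles Tibble with `region`, `profile`, `stage` (the
#'   `profiles` element of a `stage_run_report`, or one stage's
#'   [stage_region_profile()] output with a `stage` column added).
#' @return A ggplot object.
#' @export
plot_region_profile <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$region, y = .data$profile,
                               group = .data$stage, colour = .data$stage)) +
    ggplot2::geom_polygon(ggplot2::aes(fill = .data$stage), alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Regional importance", colour = "Stage",
                  fill = "Stage") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-region staging performance
#'
#' @param object A `stage_performance` tibble with a `region` column (the
#'   `performance` element of a `stage_run_report`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stage_performance
#' @export
autoplot.stage_performance <- function(object, ...) {
  df <- object |>
    dplyr::select(dplyr::any_of(c("region", "accuracy", "auc_macro",
                                  "f1_macro"))) |>
    tidyr::pivot_longer(-"region", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1 / 3, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Metric value", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of gene-confidence tiers by region
#'
#' @param tier_counts The `tier_counts` tibble of a `stage_run_report`.
#' @return A ggplot object.
#' @export
plot_confidence_tiers <- function(tier_counts) {
  df <- dplyr::filter(tier_counts, .data$confidence != "Excluded")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$n_genes,
                                   fill = .data$confidence)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "Genes", fill = "Confidence") +
    ggplot2::theme_minimal()
}
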