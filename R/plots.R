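#' Plot a PCoA ordination
#'
#' Scatterplot of the first two principal coordinate axes, optionally
#' coloured by a metadata variable.
#'
#' @param object A `subotu_pcoa` object.
#' @param metadata Optional tibble with `sample_id` and grouping columns.
#' @param colour Name of the metadata column to colour by.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subotu_pcoa <- function(object, metadata = NULL, colour = NULL,
                                 ...) {
  df <- object$points
  if (!is.null(metadata)) df <- dplyr::left_join(df, metadata, by = "sample_id")
  pct <- round(100 * object$proportion_explained[1:2], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 3)
  } else {
    p <- p + ggplot2::geom_point(size = 3)
  }
  p +
    ggplot2::labs(x = paste0("PCoA1 (", pct[1], "%)"),
                  y = paste0("PCoA2 (", pct[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Plot a CCA triplot
#'
#' Sites and taxa as points, environmental variables as arrows from the
#' origin (scaling-2 scores).
#'
#' @param object A `subotu_cca` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subotu_cca <- function(object, ...) {
  ax <- colnames(object$site_scores)[2:3]
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = object$site_scores,
      ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]]), colour = "grey40"
    ) +
    ggplot2::geom_text(
      data = object$taxon_scores,
      ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]], label = .data$taxon),
      colour = "firebrick", size = 3
    ) +
    ggplot2::geom_segment(
      data = object$biplot_scores,
      ggplot2::aes(x = 0, y = 0, xend = .data[[ax[1]]],
                   yend = .data[[ax[2]]]),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "steelblue"
    ) +
    ggplot2::geom_text(
      data = object$biplot_scores,
      ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]], label = .data$variable),
      colour = "steelblue", vjust = -0.6, size = 3
    ) +
    ggplot2::labs(x = "CCA1", y = "CCA2") +
    ggplot2::theme_minimal()
}

#' Stacked composition barplot
#'
#' Bars per sample of the taxa retained by the barplot display transform
#' (mean relative abundance above the threshold, remainder pooled as
#' `"Other"`).
#'
#' @param barplot_table Output of [display_transforms()] in `"barplot"` mode.
#' @return A ggplot object.
#' @export
plot_composition <- function(barplot_table) {
  long <- tidyr::pivot_longer(barplot_table, -"taxon",
                              names_to = "sample_id",
                              values_to = "abundance")
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$abundance,
                                     fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Relative abundance", fill = "Taxon") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Abundance heatmap
#'
#' Tile heatmap of the log/z-score display transform.
#'
#' @param heatmap_table Output of [display_transforms()] in `"heatmap"` mode.
#' @return A ggplot object.
#' @export
plot_heatmap <- function(heatmap_table) {
  label_col <- intersect(c("taxon", "feature_id"), names(heatmap_table))[1]
  long <- heatmap_table %>%
    dplyr::select(-dplyr::any_of("flat")) %>%
    tidyr::pivot_longer(dplyr::where(is.numeric), names_to = "sample_id",
                        values_to = "z")
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data[[label_col]],
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
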