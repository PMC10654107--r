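# ggplot2 visualizations for the pipeline's result types.

#' Plot a protein-family accumulation curve
#'
#' Median distinct-family count per sample size with an interquartile
#' ribbon.
#'
#' @param curve Tibble from [accumulation_curve()].
#' @return A ggplot object.
#' @export
plot_accumulation_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k,
                                      y = .data$median_families)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "genomes sampled", y = "distinct protein families",
                  title = "Protein-family accumulation") +
    ggplot2::theme_minimal()
}

#' @rdname plot_accumulation_curve
#' @param object A `pf_accumulation` tibble.
#' @param ... Unused.
#' @export
autoplot.pf_accumulation <- function(object, ...) {
  plot_accumulation_curve(object)
}

#' Heatmap of pairwise strict Robinson-Foulds values
#'
#' @param m Symmetric sRFV matrix from [srfv_matrix()].
#' @return A ggplot object.
#' @export
plot_srfv_heatmap <- function(m) {
  df <- tibble::as_tibble(m, rownames = "tree_a") |>
    tidyr::pivot_longer(-"tree_a", names_to = "tree_b",
                        values_to = "srfv")
  ggplot2::ggplot(df, ggplot2::aes(.data$tree_a, .data$tree_b,
                                   fill = .data$srfv)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$srfv)), size = 3) +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "sRFV",
                  title = "Co-phylogeny (0 = identical topology)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Heatmap of intergenomic similarity with rank assignments
#'
#' @param sim Similarity matrix from [similarity_matrix()].
#' @return A ggplot object.
#' @export
plot_similarity_heatmap <- function(sim) {
  ord <- rownames(sim)[stats::hclust(stats::as.dist(100 - sim))$order]
  df <- tibble::as_tibble(sim, rownames = "genome_a") |>
    tidyr::pivot_longer(-"genome_a", names_to = "genome_b",
                        values_to = "similarity") |>
    dplyr::mutate(genome_a = factor(.data$genome_a, levels = ord),
                  genome_b = factor(.data$genome_b, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(.data$genome_a, .data$genome_b,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity (%)",
                  title = "Intergenomic similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot inter-block direct information with the top fraction highlighted
#'
#' @param object A `dca_result`.
#' @param top_fraction Highlighted fraction (default 0.01).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dca_result <- function(object, top_fraction = 0.01, ...) {
  pairs <- tidy(object)
  n_top <- max(1, ceiling(top_fraction * nrow(pairs)))
  pairs$top <- seq_len(nrow(pairs)) <= n_top
  ggplot2::ggplot(pairs, ggplot2::aes(.data$col_a, .data$col_b,
                                      size = .data$di,
                                      colour = .data$top)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "column (protein A)", y = "column (protein B)",
                  colour = sprintf("top %.0f%%", 100 * top_fraction),
                  size = "DI (nats)",
                  title = "Inter-protein direct information") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
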