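# ggplot2 visualisations for the main result types.

#' Plot a cytokine correlation network
#'
#' Force-directed layout with edges coloured by correlation sign and sized
#' by `|r|`; nodes coloured by functional category. Isolated analytes are
#' drawn translucent.
#'
#' @param object A [build_network()] result.
#' @param seed,iterations Passed to [layout_force_directed()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cytokine_network <- function(object, seed = 1L, iterations = 200L, ...) {
  coords <- layout_force_directed(object, seed = seed, iterations = iterations)
  nodes <- dplyr::left_join(object$nodes, coords, by = "analyte")
  edges <- object$edges |>
    dplyr::left_join(coords, by = c(analyte_a = "analyte")) |>
    dplyr::rename(x_a = "x", y_a = "y") |>
    dplyr::left_join(coords, by = c(analyte_b = "analyte")) |>
    dplyr::rename(x_b = "x", y_b = "y")
  p <- ggplot2::ggplot()
  if (nrow(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x_a, y = .data$y_a, xend = .data$x_b,
                   yend = .data$y_b, colour = .data$sign,
                   linewidth = abs(.data$r)), alpha = 0.6) +
      ggplot2::scale_colour_manual(values = c("+" = "#c0392b", "-" = "#2980b9"),
                                   name = "correlation") +
      ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none")
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$category,
                                     alpha = .data$degree > 0),
                        shape = 21, size = 4) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$analyte),
                       size = 2.4, vjust = -1.2) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "category")
}

#' Plot PRS clusters in PCA space
#'
#' @param object A [kmeans_two()] result.
#' @param rank_matrix The rank matrix the clustering was run on (for the
#'   PCA projection).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.prs_clusters <- function(object, rank_matrix, ...) {
  pc <- pca_project(rank_matrix)
  dat <- dplyr::left_join(pc$coords, object$assignment, by = "cdr3_aa")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                    colour = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pc$var_explained[1]),
      y = if (length(pc$var_explained) > 1)
        sprintf("PC2 (%.1f%%)", 100 * pc$var_explained[2]) else "PC2",
      colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot per-patient clone sharing
#'
#' Shared vs unique clone percentages per patient for one recovery
#' direction.
#'
#' @param summary A [sharing_summary()] result.
#' @param direction `"pct_shared_of_blood"` or `"pct_shared_of_csf"`.
#' @return A ggplot object.
#' @export
plot_sharing <- function(summary,
                         direction = c("pct_shared_of_csf", "pct_shared_of_blood")) {
  direction <- match.arg(direction)
  stopifnot(inherits(summary, "sharing_summary"))
  dat <- summary$patients |>
    dplyr::mutate(shared = .data[[direction]], unique = 100 - .data$shared) |>
    tidyr::pivot_longer(c("shared", "unique"), names_to = "status",
                        values_to = "pct")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$patient_id, y = .data$pct,
                                    fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(. ~ group, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(shared = "#c0392b", unique = "#2980b9")) +
    ggplot2::labs(x = NULL, y = "% of clones", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
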