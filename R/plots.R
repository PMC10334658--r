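#' Boxplots of alpha-diversity indices by group
#'
#' @param object A `microrewire_alpha` table (from [alpha_table()]) with
#'   group metadata.
#' @param ... Unused.
#' @return A ggplot: one facet per index, boxplots of case vs control.
#' @export
autoplot.microrewire_alpha <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("observed", "shannon", "simpson"),
                        names_to = "index", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Alpha diversity") +
    ggplot2::theme_minimal()
}

#' Ordination scatter plot of a PCoA result
#'
#' @param object A `microrewire_pcoa` (from [pcoa()]).
#' @param groups Optional group label per sample for coloring.
#' @param ... Unused.
#' @return A ggplot of the first two axes with percent variance labels.
#' @export
autoplot.microrewire_pcoa <- function(object, groups = NULL, ...) {
  df <- tidy(object)
  if (!is.null(groups)) df$group <- groups
  lab <- function(i) sprintf("Axis %d (%.1f%%)", i, 100 * object$prop_explained[i])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2))
  p <- if (is.null(groups)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.7)
  }
  p + ggplot2::labs(x = lab(1L), y = lab(2L)) + ggplot2::theme_minimal()
}

#' Plot a differential network with edges colored by rewiring class
#'
#' Nodes are laid out with a deterministic (seeded) Fruchterman-Reingold
#' layout; gained, lost and changed-direction edges are distinguished by
#' color and linetype, mirroring the usual rewired-network figures.
#'
#' @param object A `differential_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.differential_network <- function(object, seed = 1L, ...) {
  g <- as_undirected_graph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(node = igraph::V(g)$name, x = xy[, 1L], y = xy[, 2L])
  e <- object$edges |>
    left_join(nodes, by = c(taxon_a = "node")) |>
    dplyr::rename(xa = "x", ya = "y") |>
    left_join(nodes, by = c(taxon_b = "node")) |>
    dplyr::rename(xb = "x", yb = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, colour = .data$class,
                   linetype = .data$class),
      linewidth = 0.4
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
                       vjust = -0.8, size = 2.5) +
    ggplot2::scale_colour_manual(values = c(
      gained = "#2e7d32", lost = "#c62828", changed_direction = "#1565c0"
    )) +
    ggplot2::scale_linetype_manual(values = c(
      gained = "solid", lost = "dashed", changed_direction = "dotdash"
    )) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "rewiring", linetype = "rewiring")
}

#' Plot a k-NN distance profile with its knee
#'
#' @param profile Sorted distances from [knn_distance_profile()].
#' @return A ggplot with the knee-selected eps marked.
#' @export
plot_knn_profile <- function(profile) {
  df <- tibble(rank = seq_along(profile), distance = profile)
  eps <- knee_eps(profile)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$distance)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = eps, linetype = "dashed") +
    ggplot2::labs(x = "Points sorted by k-NN distance", y = "k-NN distance") +
    ggplot2::theme_minimal()
}
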