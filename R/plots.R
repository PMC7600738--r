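# ggplot2 display helpers for chemical-space maps.

#' Plot a chemical-space tree layout
#'
#' Draws the spanning-tree map: edges between tree neighbors, nodes at
#' their [tree_layout()] coordinates, optionally colored by an annotation
#' column (continuous properties work well as average ranks; see
#' [average_rank()] and [clamp_for_display()]).
#'
#' @param layout Tibble from [tree_layout()] (`id`, `x`, `y`).
#' @param tree The [mst_kruskal()] tree the layout was computed from.
#' @param annotations Optional tibble with `compound_id` and annotation
#'   columns.
#' @param colour Name of the annotation column to color nodes by.
#' @return A ggplot object.
#' @export
plot_chemspace <- function(layout, tree, annotations = NULL, colour = NULL) {
  seg <- dplyr::left_join(tibble::as_tibble(tree)[, c("from", "to")],
                          layout, by = c("from" = "id")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(layout, by = c("to" = "id"))
  pts <- layout
  if (!is.null(annotations)) {
    pts <- dplyr::left_join(pts, annotations, by = c("id" = "compound_id"))
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x, yend = .data$y),
                          colour = "grey70", linewidth = 0.3)
  if (!is.null(colour) && colour %in% names(pts)) {
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(x = .data$x, y = .data$y,
                                              colour = .data[[colour]]),
                                 size = 1.5)
  } else {
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 size = 1.5)
  }
  p + ggplot2::theme_void() + ggplot2::labs(colour = colour)
}
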