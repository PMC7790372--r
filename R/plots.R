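# Shared layout helper: Fruchterman-Reingold coordinates as a tibble.
graph_layout_tbl <- function(g, seed = 42) {
  xy <- with_seed_(seed, igraph::layout_with_fr(g))
  tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
}

graph_edges_tbl <- function(g, layout) {
  ends <- igraph::as_edgelist(g, names = TRUE)
  if (!nrow(ends)) {
    return(tibble(x = numeric(), y = numeric(), xend = numeric(),
                  yend = numeric()))
  }
  tibble(
    x = layout$x[match(ends[, 1], layout$name)],
    y = layout$y[match(ends[, 1], layout$name)],
    xend = layout$x[match(ends[, 2], layout$name)],
    yend = layout$y[match(ends[, 2], layout$name)]
  )
}

#' Plot a sequence similarity network
#'
#' Force-directed layout with nodes coloured by functional label.
#'
#' @param object An `ssn`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ssn <- function(object, seed = 42, ...) {
  lay <- graph_layout_tbl(object$graph, seed)
  lay <- left_join(lay, object$nodes, by = c(name = "id"))
  ed <- graph_edges_tbl(object$graph, lay)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$label), size = 1.5) +
    ggplot2::labs(colour = "label",
                  title = sprintf("SSN: %d nodes, %d edges",
                                  nrow(object$nodes), nrow(object$edges))) +
    ggplot2::theme_void()
}

#' Plot a pivot network
#'
#' One node per cluster (area proportional to cluster size), coloured by
#' label.
#'
#' @param object A `pivot_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pivot_network <- function(object, seed = 42, ...) {
  lay <- graph_layout_tbl(object$graph, seed)
  nodes <- object$nodes %>% mutate(name = as.character(.data$cluster_id))
  lay <- left_join(lay, nodes, by = "name")
  ed <- graph_edges_tbl(object$graph, lay)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60", linewidth = 0.4) +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$size,
                                     colour = .data$label)) +
    ggplot2::geom_text(data = lay,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       vjust = -1.1, size = 3) +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::theme_void()
}

#' Plot a motif as a stacked probability logo
#'
#' Per-column stacked bars of residue probabilities (residues below
#' `min_prob` are pooled into an unlabelled remainder), a plain-ggplot
#' stand-in for a sequence logo.
#'
#' @param object A `nat_motif`.
#' @param min_prob Smallest residue probability drawn with its own fill.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nat_motif <- function(object, min_prob = 0.05, ...) {
  df <- tidy(object) %>%
    mutate(residue = ifelse(.data$prob >= min_prob, .data$residue, "other")) %>%
    group_by(.data$position, .data$residue) %>%
    summarise(prob = sum(.data$prob), .groups = "drop") %>%
    arrange(.data$position, desc(.data$prob))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position), y = .data$prob,
                                   fill = .data$residue)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(x = "motif position", y = "probability",
                  title = sprintf("%s  (%s)", object$name,
                                  regex_from_motif(object))) +
    ggplot2::theme_minimal()
}

#' Plot a small-world grid scan
#'
#' Largest-component size against the score threshold, one line per
#' E-value cutoff, points marked by small-world status.
#'
#' @param object Output tibble of [grid_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_grid_scan <- function(object, ...) {
  df <- object %>% mutate(evalue = factor(.data$evalue_max))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score_min,
                                   y = .data$largest_component_size,
                                   colour = .data$evalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$is_smallworld), size = 3) +
    ggplot2::labs(x = "minimum edge score", y = "largest component size",
                  colour = "E-value max", shape = "small-world") +
    ggplot2::theme_minimal()
}
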