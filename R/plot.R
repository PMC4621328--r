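#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# simple tidy tree layout: leaves evenly spaced, internal nodes centred
# over their children, depth on the vertical axis
tree_layout <- function(tr) {
  n <- length(tr$term)
  x <- rep(NA_real_, n)
  leaves <- which(lengths(tr$children) == 0L)
  x[leaves] <- seq_along(leaves)
  for (v in rev(seq_len(n))) {
    if (is.na(x[v])) x[v] <- mean(x[tr$children[[v]]])
  }
  tibble::tibble(node = tr$term, x = x, y = -tr$depth,
                 parent = ifelse(tr$parent > 0L, tr$term[pmax(tr$parent, 1L)],
                                 NA_character_))
}

#' Plot an integrated ontology
#'
#' Draws the merged tree with nodes coloured by how many source ontologies
#' they combine and sized by their closeness weight. Intended for small
#' results; large integrations are better summarised with
#' [glance.integrated_ontology()].
#'
#' @param object An [integrated_ontology].
#' @param label Label nodes with their members (default for trees up to 60
#'   nodes).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.integrated_ontology <- function(object,
                                         label = n_vertices(object$tree) <= 60L,
                                         ...) {
  lay <- tree_layout(object$tree)
  td <- tidy(object)
  lay$members <- td$members[match(lay$node, td$node)]
  lay$n_members <- td$n_members[match(lay$node, td$node)]
  lay$weight <- td$weight[match(lay$node, td$node)]
  seg <- dplyr::inner_join(
    lay,
    dplyr::select(lay, parent_node = "node", xend = "x", yend = "y"),
    by = c(parent = "parent_node")
  )
  p <- ggplot2::ggplot(lay, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(xend = .data$xend, yend = .data$yend),
      colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$n_members),
                                     size = .data$weight)) +
    ggplot2::scale_size_continuous(range = c(1.5, 5)) +
    ggplot2::labs(colour = "members", size = "node weight",
                  x = NULL, y = "depth",
                  title = sprintf("Integrated ontology {%s}, cohesion %.4g",
                                  paste(object$sources, collapse = ", "),
                                  object$total_cohesion)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  if (label) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = ifelse(.data$members == "", "(root)",
                                  .data$members)),
      size = 2.6, vjust = -1)
  }
  p
}

#' Plot mean cohesion of multi-integration strategies
#'
#' Companion to benchmark tables produced from [benchmark_suite()] runs: a
#' line per strategy over ontology size (or count).
#'
#' @param results A data frame with columns `strategy`, `size` and
#'   `cohesion` (one row per run).
#' @return A ggplot object.
#' @export
plot_strategy_cohesion <- function(results) {
  stopifnot(all(c("strategy", "size", "cohesion") %in% names(results)))
  summ <- results |>
    dplyr::group_by(.data$strategy, .data$size) |>
    dplyr::summarise(cohesion = mean(.data$cohesion), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$size, y = .data$cohesion,
                                     colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ontology size (vertices)", y = "mean total cohesion",
                  colour = "strategy") +
    ggplot2::theme_minimal()
}
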