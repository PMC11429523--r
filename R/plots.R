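#' Plot knowledge-graph composition
#'
#' Bar panels of entity counts per category and statement counts per
#' knowledge pattern and edge class.
#'
#' @param object A `cond_kg`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cond_kg <- function(object, ...) {
  ent <- dplyr::count(object$entities, .data$category)
  cls <- tibble::tibble(class = if (nrow(object$statements))
    kg_edge_class(object, object$statements$statement_id) else character()) |>
    dplyr::count(.data$class)
  dat <- dplyr::bind_rows(
    dplyr::mutate(ent, panel = "entities", key = .data$category),
    dplyr::mutate(cls, panel = "statement edge classes", key = .data$class)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$key, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "count",
                  title = "Knowledge graph composition") +
    ggplot2::theme_minimal()
}

#' Plot a subgraph as a node-link diagram
#'
#' Entities, gates, and relation nodes of the reified form are laid out on a
#' deterministic circle; `from`/`to`/`member` edges are drawn as segments.
#'
#' @param object A `kg_subgraph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kg_subgraph <- function(object, ...) {
  g <- object$graph
  pg <- reify(g)
  nodes <- pg$nodes[pg$nodes$kind != "auxiliary", ]
  nodes <- nodes[order(nodes$node_id, method = "radix"), ]
  n <- nrow(nodes)
  theta <- if (n) 2 * pi * (seq_len(n) - 1L) / n else numeric()
  layout <- tibble::tibble(
    node_id = nodes$node_id, kind = nodes$kind,
    label = ifelse(is.na(nodes$name), ifelse(is.na(nodes$predicate),
                                             nodes$gate_type, nodes$predicate),
                   nodes$name),
    x = cos(theta), y = sin(theta))
  edges <- pg$edges[pg$edges$label != "evidence", ]
  seg <- dplyr::inner_join(edges, layout[, c("node_id", "x", "y")],
                           by = c(source = "node_id")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::inner_join(layout[, c("node_id", "x", "y")], by = c(target = "node_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y),
      colour = "grey70") +
    ggplot2::geom_point(data = layout,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$kind, shape = .data$kind),
      size = 3) +
    ggplot2::geom_text(data = layout,
      ggplot2::aes(x = .data$x * 1.12, y = .data$y * 1.12, label = .data$label),
      size = 2.8) +
    ggplot2::coord_equal(xlim = c(-1.35, 1.35), ylim = c(-1.35, 1.35)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste("Subgraph around",
                                paste(object$roots, collapse = ", ")))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a personalized suggestion report
#'
#' @param suggestions A tibble from [personalized_suggestions()].
#' @return A ggplot object: drugs against their condition-matched labels.
#' @export
plot_suggestions <- function(suggestions) {
  ggplot2::ggplot(suggestions,
    ggplot2::aes(x = .data$label, y = .data$drug, fill = .data$label)) +
    ggplot2::geom_tile(colour = "white", show.legend = FALSE) +
    ggplot2::labs(x = "suggestion label", y = NULL,
                  title = "Personalized drug suggestions") +
    ggplot2::theme_minimal()
}
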