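#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot alignment telemetry
#'
#' Bar chart of per-heuristic multi-candidate win counts.
#'
#' @param object A `tax_alignment`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tax_alignment
#' @export
autoplot.tax_alignment <- function(object, ...) {
  df <- object$telemetry
  df$heuristic <- factor(df$heuristic, levels = rev(df$heuristic))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wins, y = .data$heuristic)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "multi-candidate wins", y = NULL,
                  title = sprintf("Deciding heuristics: %s → %s",
                                  object$src_tag, object$ws_tag)) +
    ggplot2::theme_minimal()
}

#' Plot source-node fates from a merge report
#'
#' Stacked bars of node fates (copied / aligned / absorbed / conflict /
#' ambiguous) per source.
#'
#' @param object A merge-report tibble (`tax_merge_report`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tax_merge_report
#' @export
autoplot.tax_merge_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("source", "copied", "aligned", "absorbed",
                        "conflict", "ambiguous")],
    -"source", names_to = "fate", values_to = "nodes"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$source, y = .data$nodes,
                                     fill = .data$fate)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "source nodes") +
    ggplot2::theme_minimal()
}

#' Draw a taxonomy as a simple cladogram
#'
#' Rectangular cladogram with tip labels; intended for the small
#' taxonomies used in examples and vignettes.
#'
#' @param t A single-rooted taxonomy.
#' @param label_tips Draw tip names.
#' @return A ggplot.
#' @export
plot_taxonomy <- function(t, label_tips = TRUE) {
  tips <- sort(tax_tip_ids(t))
  y <- stats::setNames(rep(NA_real_, node_count(t)), t$nodes$id)
  y[as.character(tips)] <- seq_along(tips)
  for (id in tax_postorder(t)) {
    key <- as.character(id)
    if (is.na(y[[key]])) {
      y[[key]] <- mean(y[as.character(tax_children_ids(t, id))])
    }
  }
  x <- tax_depths(t)
  nd <- t$nodes
  df <- tibble(id = nd$id, name = nd$name,
               x = unname(x[as.character(nd$id)]),
               y = unname(y[as.character(nd$id)]),
               parent = nd$parent)
  seg <- dplyr::filter(df, !is.na(.data$parent))
  seg$px <- df$x[match(seg$parent, df$id)]
  seg$py <- df$y[match(seg$parent, df$id)]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$px, y = .data$py,
                                       xend = .data$px, yend = .data$y)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$px, y = .data$y,
                                       xend = .data$x, yend = .data$y)) +
    ggplot2::theme_void()
  if (label_tips) {
    p <- p + ggplot2::geom_text(
      data = dplyr::filter(df, .data$id %in% tips),
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      hjust = 0, nudge_x = 0.05, size = 3
    ) +
      ggplot2::expand_limits(x = max(df$x) + 1.5)
  }
  p
}
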