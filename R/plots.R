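# ggplot2 visualizations for the result types.

#' Plot an enrichment result
#'
#' Horizontal bar chart of -log10 p-values for the top terms, colored by
#' FDR significance.
#'
#' @param object An `enrichment_result`.
#' @param n_terms Number of top terms to show (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, n_terms = 15, ...) {
  df <- as_tibble(object) |>
    arrange(.data$p_value) |>
    head(n_terms) |>
    mutate(label = sprintf("%s (%s)", .data$term_name, .data$term_id))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value),
                                   y = stats::reorder(.data$label, -.data$p_value),
                                   fill = .data$significant_fdr)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL, fill = "FDR sig.") +
    ggplot2::theme_minimal()
}

#' Plot per-level merge statistics
#'
#' Bar chart of left rows first matched at each merge level, with the
#' unmatched remainder appended.
#'
#' @param object A `merge_report` or `merge_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.merge_report <- function(object, ...) {
  df <- bind_rows(
    object$levels |>
      mutate(label = sprintf("L%d: %s~%s", .data$level, .data$left_column,
                             .data$right_column)) |>
      select("label", count = "matched"),
    tibble(label = "unmatched", count = object$left_unmatched))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$label, levels = df$label),
                                   y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "left rows", title = "Merge level attribution") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.merge_report
#' @export
autoplot.merge_result <- function(object, ...) {
  autoplot(object$report, ...)
}

#' Plot consensus target agreement counts
#'
#' Bar chart of consensus rows by number of supporting sources.
#'
#' @param object A `consensus_targets` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_targets <- function(object, ...) {
  df <- count(as_tibble(object), .data$agreement_count)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$agreement_count), y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "supporting sources", y = "predictions",
                  title = sprintf("Consensus targets (level = %s)",
                                  attr(object, "level"))) +
    ggplot2::theme_minimal()
}

#' Plot a centroid dendrogram
#'
#' Segment plot of the merge tree; inverted merges are drawn in red.
#'
#' @param object A `centroid_dendrogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.centroid_dendrogram <- function(object, ...) {
  n <- object$n
  xpos <- numeric(n + nrow(object$merges))
  xpos[object$order] <- seq_len(n)
  hts <- numeric(n + nrow(object$merges))
  segs <- list()
  for (i in seq_len(nrow(object$merges))) {
    m <- object$merges[i, ]
    a <- m$node_a; b <- m$node_b; new <- m$new_node
    xpos[new] <- (xpos[a] + xpos[b]) / 2
    hts[new] <- m$height
    segs[[length(segs) + 1]] <- tibble(
      x = c(xpos[a], xpos[b], xpos[a]),
      xend = c(xpos[a], xpos[b], xpos[b]),
      y = c(hts[a], hts[b], m$height),
      yend = c(m$height, m$height, m$height),
      inversion = m$inversion)
  }
  segs <- bind_rows(segs)
  labels_df <- tibble(x = xpos[seq_len(n)], label = object$labels)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend,
                                       color = .data$inversion)) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey20", `TRUE` = "red"),
                                guide = "none") +
    ggplot2::geom_text(data = labels_df,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.1, size = 2.5) +
    ggplot2::labs(x = NULL, y = "merge height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
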