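# Broom-style tidiers for the package's result objects.

#' Tidy a merge report
#'
#' @param x A `merge_report` or `merge_result`.
#' @param ... Unused.
#' @return A tibble with one row per merge level (`level`, `left_column`,
#'   `right_column`, `translated`, `matched`).
#' @export
tidy.merge_report <- function(x, ...) {
  x$levels
}

#' @rdname tidy.merge_report
#' @export
tidy.merge_result <- function(x, ...) {
  tidy(x$report)
}

#' Summarize a merge in one row
#'
#' @param x A `merge_report` or `merge_result`.
#' @param ... Unused.
#' @return A one-row tibble: `mode`, `left_n`, `right_n`, `matched_total`,
#'   `matched_rows`, `left_unmatched`, `right_unmatched`.
#' @export
glance.merge_report <- function(x, ...) {
  tibble(mode = x$mode, left_n = x$left_n, right_n = x$right_n,
         matched_total = x$matched_total, matched_rows = x$matched_rows,
         left_unmatched = x$left_unmatched, right_unmatched = x$right_unmatched)
}

#' @rdname glance.merge_report
#' @export
glance.merge_result <- function(x, ...) {
  glance(x$report)
}

#' Summarize an enrichment result in one row
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return A one-row tibble: `n_sets`, `n_significant`, `n_significant_fdr`,
#'   `min_p`, `alpha`, `n_query`, `n_dropped`.
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_sets = nrow(x),
         n_significant = sum(x$significant),
         n_significant_fdr = sum(x$significant_fdr),
         min_p = if (nrow(x) > 0) min(x$p_value) else NA_real_,
         alpha = attr(x, "alpha"),
         n_query = attr(x, "n_query"),
         n_dropped = attr(x, "n_dropped"))
}

#' Tidy a dendrogram's merge sequence
#'
#' @param x A `centroid_dendrogram`.
#' @param ... Unused.
#' @return The merge tibble (`step`, `node_a`, `node_b`, `height`,
#'   `new_node`, `inversion`).
#' @export
tidy.centroid_dendrogram <- function(x, ...) {
  x$merges
}

#' Summarize a dendrogram in one row
#'
#' @param x A `centroid_dendrogram`.
#' @param ... Unused.
#' @return A one-row tibble: `n_leaves`, `n_merges`, `n_inversions`,
#'   `max_height`.
#' @export
glance.centroid_dendrogram <- function(x, ...) {
  tibble(n_leaves = x$n, n_merges = nrow(x$merges),
         n_inversions = sum(x$merges$inversion),
         max_height = max(x$merges$height))
}

#' Summarize a workflow run in one row
#'
#' @param x A `workflow_result`.
#' @param ... Unused.
#' @return A one-row tibble with the headline counts of the run.
#' @export
glance.workflow_result <- function(x, ...) {
  tibble(n_query_mirnas = if (is.null(x$homology)) NA_integer_ else
           length(unique(x$homology$id_b[x$homology$pass])),
         n_consensus = nrow(x$targets),
         matched_total = x$report$matched_total,
         n_merged_rows = nrow(x$merged),
         n_enriched = sum(x$enrichment$significant),
         min_enrichment_p = if (nrow(x$enrichment) > 0) min(x$enrichment$p_value) else NA_real_)
}
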