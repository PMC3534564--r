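# Spreadsheet-style table operations and the ordered multi-level merge
# engine. Experiment tables are ordinary tibbles carrying a stable `.row_id`
# assigned at load; all operations preserve it.

#' Coerce to an experiment table
#'
#' Adds a stable `.row_id` column (original row order) if absent and checks
#' that column names are unique.
#'
#' @param x A data frame.
#' @return A tibble with a `.row_id` integer column.
#' @export
as_experiment_table <- function(x) {
  x <- as_tibble(x)
  if (anyDuplicated(names(x))) abort("column names must be unique")
  if (!".row_id" %in% names(x)) {
    x <- mutate(x, .row_id = dplyr::row_number(), .before = 1)
  }
  if (anyDuplicated(x$.row_id)) abort("`.row_id` values must be unique")
  x
}

#' Read an experiment table from TSV
#'
#' Reads a tab-separated file (`NA` missing token, `#` comment lines allowed)
#' with column types guessed, and assigns `.row_id`.
#'
#' @param path Path to a TSV file.
#' @return An experiment table (tibble with `.row_id`).
#' @export
load_experiment_table <- function(path) {
  tbl <- readr::read_tsv(path, na = "NA", comment = "#", progress = FALSE,
                         show_col_types = FALSE)
  as_experiment_table(tbl)
}

#' Define one merge relation
#'
#' A relation names the key column on each side and, optionally, an
#' identifier translation applied to the *left* key via [xref()] before
#' comparison (e.g. translate a left Entrez column to gene symbols to match a
#' right symbol column).
#'
#' @param left_column,right_column Key column names.
#' @param translate_from,translate_to Optional namespaces for left-key
#'   translation.
#' @param species Species for the translation lookup (required with
#'   translation).
#' @param case_insensitive Compare keys case-insensitively. Default: `TRUE`
#'   when the effective key namespace is `gene_symbol` (i.e. the translation
#'   target is `gene_symbol`, or no translation and the left column name
#'   contains "symbol"), otherwise exact.
#' @return A `merge_relation` object.
#' @export
merge_relation <- function(left_column, right_column = left_column,
                           translate_from = NULL, translate_to = NULL,
                           species = NULL, case_insensitive = NULL) {
  if (xor(is.null(translate_from), is.null(translate_to))) {
    abort("`translate_from` and `translate_to` must be given together")
  }
  if (!is.null(translate_from)) {
    assert_namespace(translate_from, "translate_from")
    assert_namespace(translate_to, "translate_to")
    if (is.null(species)) abort("`species` is required when a relation translates")
    assert_species(species)
  }
  if (is.null(case_insensitive)) {
    case_insensitive <- identical(translate_to, "gene_symbol") ||
      (is.null(translate_to) && grepl("symbol", left_column, ignore.case = TRUE))
  }
  structure(list(left_column = left_column, right_column = right_column,
                 translate_from = translate_from, translate_to = translate_to,
                 species = species, case_insensitive = isTRUE(case_insensitive)),
            class = "merge_relation")
}

#' Define a multi-level merge plan
#'
#' @param ... One or more [merge_relation()]s, applied in order: a left row
#'   matched at one relation is excluded from all later relations.
#' @param mode `"intersection"` (matched rows only) or `"union"` (matched
#'   rows plus unmatched rows from both sides, `NA`-filled).
#' @param output_columns Optional character vector selecting output columns
#'   (after `_left`/`_right` collision suffixing).
#' @return A `merge_plan` object.
#' @export
merge_plan <- function(..., mode = c("intersection", "union"),
                       output_columns = NULL) {
  relations <- list(...)
  if (length(relations) == 0) abort("a merge plan needs at least one relation")
  if (!all(map_lgl(relations, inherits, "merge_relation"))) {
    abort("all `...` arguments must be merge_relation objects")
  }
  mode <- match.arg(mode)
  structure(list(relations = relations, mode = mode,
                 output_columns = output_columns),
            class = "merge_plan")
}

# Long (row, key) pairs for one side of a relation. NA keys never match.
relation_keys <- function(values, row_ids, rel, side, snapshot) {
  keys <- tibble(.rid = row_ids, key = as.character(values))
  if (side == "left" && !is.null(rel$translate_from)) {
    if (is.null(snapshot)) {
      abort("merge plan uses identifier translation but no snapshot was supplied")
    }
    vals <- unique(keys$key[!is.na(keys$key)])
    m <- xref(vals, rel$translate_from, rel$translate_to, rel$species, snapshot)
    m <- filter(m, .data$matched)
    keys <- keys |>
      inner_join(m, by = c(key = "input_id"), relationship = "many-to-many") |>
      transmute(.rid = .data$.rid, key = .data$output_id)
  }
  keys <- filter(keys, !is.na(.data$key))
  if (rel$case_insensitive) keys$key <- tolower(keys$key)
  keys
}

#' Merge two tables through an ordered cascade of relations
#'
#' Applies the plan's relations in order. At each level, left rows not yet
#' matched are compared with *all* right rows on that relation's keys;
#' one-to-many key matches produce one output row per matching right row
#' (cartesian within key). A left row, once matched, is excluded from later
#' levels and counted exactly once, at its earliest matching level.
#' Intersection mode returns only matched rows; union mode appends unmatched
#' left and right rows with `NA` fill. Column name collisions are resolved by
#' suffixing `_left`/`_right`.
#'
#' @param left,right Data frames (coerced via [as_experiment_table()]).
#' @param plan A [merge_plan()].
#' @param snapshot A `mirna_snapshot`; required only when a relation
#'   translates identifiers.
#' @return A `merge_result`: list with `merged` (tibble, including a
#'   `.merge_level` column, `NA` for unmatched rows) and `report` (a
#'   `merge_report`).
#' @export
#' @examples
#' left <- tibble::tibble(sym = c("TP53", NA), entrez = c("7157", "999"),
#'                        val = c(1.2, 0.5))
#' right <- tibble::tibble(sym = c("TP53", "BRCA2"), p = c(0.01, 0.2))
#' res <- merge_datasets(left, right,
#'                       merge_plan(merge_relation("sym"), mode = "union"))
#' res$merged
merge_datasets <- function(left, right, plan, snapshot = NULL) {
  stopifnot(inherits(plan, "merge_plan"))
  left <- as_experiment_table(left)
  right <- as_experiment_table(right)
  for (rel in plan$relations) {
    if (!rel$left_column %in% names(left)) {
      abort(sprintf("relation column `%s` is missing from the left table", rel$left_column))
    }
    if (!rel$right_column %in% names(right)) {
      abort(sprintf("relation column `%s` is missing from the right table", rel$right_column))
    }
  }

  remaining <- left$.row_id
  pair_list <- list()
  level_counts <- integer(length(plan$relations))
  for (i in seq_along(plan$relations)) {
    rel <- plan$relations[[i]]
    if (length(remaining) == 0) break
    lsub <- left[match(remaining, left$.row_id), , drop = FALSE]
    lkeys <- relation_keys(lsub[[rel$left_column]], lsub$.row_id, rel, "left", snapshot)
    rkeys <- relation_keys(right[[rel$right_column]], right$.row_id, rel, "right", snapshot)
    if (nrow(lkeys) == 0 || nrow(rkeys) == 0) next
    pairs_i <- inner_join(lkeys, rename(rkeys, .rrid = ".rid"),
                          by = "key", relationship = "many-to-many") |>
      distinct(.lrid = .data$.rid, .rrid = .data$.rrid) |>
      mutate(.merge_level = i)
    if (nrow(pairs_i) > 0) {
      matched_now <- unique(pairs_i$.lrid)
      level_counts[i] <- length(matched_now)
      remaining <- setdiff(remaining, matched_now)
      pair_list[[length(pair_list) + 1]] <- pairs_i
    }
  }
  pairs <- if (length(pair_list) > 0) bind_rows(pair_list) else {
    tibble(.lrid = integer(0), .rrid = integer(0), .merge_level = integer(0))
  }

  # Assemble output columns with collision suffixes.
  lcols <- setdiff(names(left), ".row_id")
  rcols <- setdiff(names(right), ".row_id")
  clash <- intersect(lcols, rcols)
  lout <- setNames(lcols, ifelse(lcols %in% clash, paste0(lcols, "_left"), lcols))
  rout <- setNames(rcols, ifelse(rcols %in% clash, paste0(rcols, "_right"), rcols))
  ltbl <- setNames(left[lcols], names(lout))
  rtbl <- setNames(right[rcols], names(rout))

  matched_rows <- bind_cols(
    ltbl[match(pairs$.lrid, left$.row_id), , drop = FALSE],
    rtbl[match(pairs$.rrid, right$.row_id), , drop = FALSE]) |>
    mutate(.merge_level = pairs$.merge_level)

  right_matched <- unique(pairs$.rrid)
  left_unmatched_ids <- remaining
  right_unmatched_ids <- setdiff(right$.row_id, right_matched)

  merged <- if (plan$mode == "intersection") {
    matched_rows
  } else {
    bind_rows(matched_rows,
              mutate(ltbl[match(left_unmatched_ids, left$.row_id), , drop = FALSE],
                     .merge_level = NA_integer_),
              mutate(rtbl[match(right_unmatched_ids, right$.row_id), , drop = FALSE],
                     .merge_level = NA_integer_))
  }
  if (!is.null(plan$output_columns)) {
    keep <- intersect(c(plan$output_columns, ".merge_level"), names(merged))
    merged <- merged[keep]
  }
  merged <- as_tibble(merged)

  report <- structure(list(
    levels = tibble(
      level = seq_along(plan$relations),
      left_column = map_chr(plan$relations, "left_column"),
      right_column = map_chr(plan$relations, "right_column"),
      translated = map_lgl(plan$relations, function(r) !is.null(r$translate_from)),
      matched = level_counts),
    matched_total = sum(level_counts),
    matched_rows = nrow(matched_rows),
    left_unmatched = length(left_unmatched_ids),
    right_unmatched = length(right_unmatched_ids),
    left_n = nrow(left), right_n = nrow(right),
    mode = plan$mode), class = "merge_report")

  structure(list(merged = merged, report = report), class = "merge_result")
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf("<merge_report> %s merge: %d left x %d right rows\n",
              x$mode, x$left_n, x$right_n))
  print(x$levels)
  cat(sprintf("matched_total %d (as %d output rows); left_unmatched %d; right_unmatched %d\n",
              x$matched_total, x$matched_rows, x$left_unmatched, x$right_unmatched))
  invisible(x)
}

#' @export
print.merge_result <- function(x, ...) {
  print(x$report)
  cat(sprintf("merged table: %d rows x %d columns\n", nrow(x$merged), ncol(x$merged)))
  invisible(x)
}

#' Remove duplicate rows by key
#'
#' Keeps the first occurrence (by `.row_id` order) of each key combination.
#' Rows whose keys are all `NA` are grouped together like any other key.
#'
#' @param t A data frame.
#' @param key_columns Non-empty character vector of key columns.
#' @return The deduplicated experiment table; the number of removed rows is
#'   reported via a message and the `n_removed` attribute.
#' @export
dedupe_rows <- function(t, key_columns) {
  if (length(key_columns) == 0) abort("`key_columns` must name at least one column")
  t <- as_experiment_table(t)
  missing <- setdiff(key_columns, names(t))
  if (length(missing) > 0) {
    abort(sprintf("key column `%s` does not exist", missing[1]))
  }
  out <- t |>
    arrange(.data$.row_id) |>
    distinct(across(all_of(key_columns)), .keep_all = TRUE)
  n_removed <- nrow(t) - nrow(out)
  if (n_removed > 0) inform(sprintf("removed %d duplicate row(s)", n_removed))
  attr(out, "n_removed") <- n_removed
  out
}

#' Split a delimited column into parts
#'
#' Produces as many new columns as the maximum number of parts observed;
#' rows with fewer parts are padded with `NA`. The source column is removed.
#'
#' @param t A data frame.
#' @param column Column to split.
#' @param delimiter Non-empty literal delimiter.
#' @return The experiment table with `column` replaced by `column_1`,
#'   `column_2`, ...
#' @export
split_column <- function(t, column, delimiter) {
  t <- as_experiment_table(t)
  if (!column %in% names(t)) abort(sprintf("column `%s` does not exist", column))
  if (!is.character(delimiter) || length(delimiter) != 1 || !nzchar(delimiter)) {
    abort("`delimiter` must be a non-empty string")
  }
  parts <- str_split(as.character(t[[column]]), fixed(delimiter))
  n <- max(c(1L, lengths(parts)))
  mat <- t(vapply(parts, function(p) c(p, rep(NA_character_, n - length(p))),
                  character(n)))
  if (n == 1) mat <- matrix(unlist(parts), ncol = 1)
  new_cols <- as_tibble(setNames(as.data.frame(mat, stringsAsFactors = FALSE),
                                 paste0(column, "_", seq_len(n))))
  pos <- match(column, names(t))
  bind_cols(t[seq_len(pos - 1)], new_cols, t[setdiff(seq_along(t), seq_len(pos))])
}

#' Concatenate columns into one
#'
#' Joins the named columns row-wise with `joiner`, skipping `NA` cells; a row
#' whose cells are all `NA` yields `NA`.
#'
#' @param t A data frame.
#' @param columns Columns to merge, in order.
#' @param joiner Separator string.
#' @param into Name of the new column (default: column names joined by `_`).
#' @param remove Drop the source columns (default `TRUE`).
#' @return The experiment table with the merged column appended at the first
#'   source column's position.
#' @export
merge_columns <- function(t, columns, joiner, into = paste(columns, collapse = "_"),
                          remove = TRUE) {
  t <- as_experiment_table(t)
  missing <- setdiff(columns, names(t))
  if (length(missing) > 0) abort(sprintf("column `%s` does not exist", missing[1]))
  if (length(columns) < 2) abort("`columns` must name at least two columns")
  vals <- map(columns, function(cl) as.character(t[[cl]]))
  joined <- pmap(vals, function(...) {
    cells <- c(...)
    cells <- cells[!is.na(cells)]
    if (length(cells) == 0) NA_character_ else paste(cells, collapse = joiner)
  })
  pos <- match(columns[1], names(t))
  t[[into]] <- unlist(joined)
  keep <- if (remove) setdiff(names(t), setdiff(columns, into)) else names(t)
  # Place the merged column where the first source column was.
  keep <- setdiff(keep, into)
  before <- keep[seq_len(min(pos - 1, length(keep)))]
  after <- setdiff(keep, before)
  t[c(before, into, after)]
}

#' Identifier extraction presets
#'
#' Named regular expressions recognizing common embedded identifiers.
#'
#' @return A named character vector of patterns.
#' @export
id_patterns <- function() {
  c(genbank = "[A-Z]{2}_[0-9]+(\\.[0-9]+)?",
    ensembl_gene = "ENS[A-Z]*G[0-9]{11}",
    ensembl_transcript = "ENS[A-Z]*T[0-9]{11}",
    entrez = "[0-9]+",
    go_term = "GO:[0-9]{7}")
}

#' Extract embedded identifiers from a column
#'
#' Extracts the first match of a preset or custom regular expression from
#' each cell into a new column; cells without a match get `NA`.
#'
#' @param t A data frame.
#' @param column Column to scan.
#' @param pattern A preset name (see [id_patterns()]) or a custom regular
#'   expression.
#' @param into Name of the new column (default `paste0(column, "_id")`).
#' @return The experiment table with the new column appended.
#' @export
extract_ids <- function(t, column, pattern, into = paste0(column, "_id")) {
  t <- as_experiment_table(t)
  if (!column %in% names(t)) abort(sprintf("column `%s` does not exist", column))
  presets <- id_patterns()
  rx <- if (pattern %in% names(presets)) presets[[pattern]] else pattern
  ok <- tryCatch({ grepl(rx, ""); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) abort(sprintf("invalid regular expression: `%s`", pattern))
  t[[into]] <- str_extract(as.character(t[[column]]), rx)
  t
}
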