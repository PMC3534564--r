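# Shared IO and sequence helpers.

# All snapshot tables are UTF-8, tab-separated, one header row, "NA" as the
# missing-value token.
read_table_file <- function(path, numeric_cols = character()) {
  tbl <- readr::read_tsv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         na = "NA", comment = "#", progress = FALSE)
  for (col in intersect(numeric_cols, names(tbl))) {
    tbl[[col]] <- as.numeric(tbl[[col]])
  }
  tbl
}

write_table_file <- function(tbl, path) {
  readr::write_tsv(tbl, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Default retrieval cap
#'
#' Any retrieval returning more rows than the cap is truncated with a warning.
#' The default is 500,000 rows; override globally with
#' `options(mirmerge.retrieval_cap = n)` or per call via the `max_rows`
#' argument of the retrieval functions.
#'
#' @return A positive integer row cap.
#' @export
retrieval_cap <- function() {
  cap <- getOption("mirmerge.retrieval_cap", 500000L)
  if (!is.numeric(cap) || length(cap) != 1 || cap < 1) {
    abort("option `mirmerge.retrieval_cap` must be a single positive number")
  }
  as.integer(cap)
}

# Truncate a retrieval result to `max_rows`, flagging truncation in an
# attribute and warning the caller.
apply_retrieval_cap <- function(tbl, max_rows) {
  if (nrow(tbl) > max_rows) {
    warn(sprintf("retrieval returned %d rows; truncated to the %d-row cap",
                 nrow(tbl), max_rows))
    tbl <- tbl[seq_len(max_rows), , drop = FALSE]
    attr(tbl, "truncated") <- TRUE
  } else {
    attr(tbl, "truncated") <- FALSE
  }
  tbl
}

#' Normalize a mature miRNA sequence
#'
#' Uppercases and converts DNA-alphabet input (`T`) to RNA (`U`).
#'
#' @param x Character vector of sequences.
#' @return Character vector of normalized RNA sequences.
#' @export
#' @examples
#' normalize_rna("ucgaTTacg")
normalize_rna <- function(x) {
  gsub("T", "U", toupper(x), fixed = TRUE)
}

# Stop if a normalized sequence contains characters outside {A,C,G,U};
# `labels` names the offending record in the error.
check_rna_alphabet <- function(x, labels = NULL) {
  bad <- grepl("[^ACGU]", x) & !is.na(x)
  if (any(bad)) {
    who <- if (is.null(labels)) paste0("element ", which(bad)[1]) else labels[which(bad)[1]]
    abort(sprintf("sequence for %s contains characters outside {A,C,G,U} after normalization",
                  who))
  }
  invisible(x)
}
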