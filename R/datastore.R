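# Loading and validating the local reference snapshot: a plain directory of
# TSV tables plus a two-column manifest (table_name, file_name). The snapshot
# replaces live database queries; all retrieval functions take one.

numeric_snapshot_cols <- c("pct_identity_src", "pct_identity_dst")

#' Load a reference snapshot directory
#'
#' Reads the manifest, parses every declared table, checks each against the
#' expected schema and runs referential checks (every miRNA id occurring in a
#' targets table must appear in `mirna_metadata` for its species). Tables not
#' declared in the manifest are recorded as absent, not errors. Loading is
#' read-only and idempotent. The ortholog table is additionally materialized
#' in both directions so directional queries never miss a stored pair.
#'
#' @param root_path Snapshot directory containing `manifest.tsv`.
#' @return A `mirna_snapshot` object: list with `root`, `version_tag`,
#'   `tables` (named list of tibbles), `absent` (undeclared table names) and
#'   `dangling` (tibble of unresolved miRNA references).
#' @seealso [validate_snapshot()], [generate_snapshot()]
#' @export
#' @examples
#' dir <- tempfile()
#' sp <- fixture_spec(seed = 1, n_genes = 40, n_mirnas = 6, n_conserved_pairs = 5,
#'                    n_two_source_pairs = 3, n_sig_mirnas = 6, n_sig_genes = 10,
#'                    mismatch_profile = c(identical = 3, mismatch_out_seed = 1,
#'                                         mismatch_in_seed = 1, multi_mismatch = 1))
#' generate_snapshot(sp, dir)
#' s <- load_snapshot(dir)
#' s
load_snapshot <- function(root_path) {
  manifest_path <- file.path(root_path, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest not found: no manifest.tsv in `%s`", root_path))
  }
  manifest <- read_table_file(manifest_path)
  if (!all(c("table_name", "file_name") %in% names(manifest))) {
    abort("manifest.tsv must have columns `table_name` and `file_name`")
  }
  schema <- snapshot_table_schema()
  known <- snapshot_table_names()
  unknown <- setdiff(manifest$table_name, known)
  if (length(unknown) > 0) {
    warn(sprintf("manifest declares unknown table(s): %s (ignored)",
                 paste(unknown, collapse = ", ")))
  }

  tables <- list()
  for (nm in intersect(manifest$table_name, known)) {
    fn <- manifest$file_name[match(nm, manifest$table_name)]
    path <- file.path(root_path, fn)
    if (!file.exists(path)) {
      abort(sprintf("table `%s`: file `%s` declared in manifest does not exist", nm, fn))
    }
    tbl <- read_table_file(path, numeric_cols = numeric_snapshot_cols)
    missing_cols <- setdiff(schema[[nm]], names(tbl))
    if (length(missing_cols) > 0) {
      abort(sprintf("table `%s` (%s): malformed header, missing column `%s`",
                    nm, fn, missing_cols[1]))
    }
    tables[[nm]] <- tbl
  }
  absent <- setdiff(known, names(tables))

  # Bidirectional ortholog view: stored rows plus their swapped mirror.
  if ("orthologs" %in% names(tables)) {
    o <- tables$orthologs
    swapped <- tibble(src_species = o$dst_species,
                      src_ensembl_gene = o$dst_ensembl_gene,
                      dst_species = o$src_species,
                      dst_ensembl_gene = o$src_ensembl_gene,
                      pct_identity_src = o$pct_identity_dst,
                      pct_identity_dst = o$pct_identity_src)
    tables$orthologs_bidir <- distinct(bind_rows(o, swapped))
  }

  dangling <- dangling_mirna_refs(tables)
  if (nrow(dangling) > 0) {
    n_ids <- nrow(distinct(dangling, .data$species, .data$mirna_id))
    warn(sprintf("%d dangling miRNA reference(s): targets tables mention miRNA ids absent from mirna_metadata",
                 n_ids))
  }

  version_file <- file.path(root_path, "version.txt")
  version_tag <- if (file.exists(version_file)) readLines(version_file, n = 1) else "unversioned"

  structure(list(root = normalizePath(root_path), version_tag = version_tag,
                 tables = tables, absent = absent, dangling = dangling),
            class = "mirna_snapshot")
}

# One row per distinct (table, species, mirna_id) in a targets table that has
# no mirna_metadata row for that species.
dangling_mirna_refs <- function(tables) {
  meta <- tables$mirna_metadata
  out <- tibble(table = character(0), species = character(0), mirna_id = character(0))
  if (is.null(meta)) return(out)
  for (nm in grep("^targets_", names(tables), value = TRUE)) {
    miss <- tables[[nm]] |>
      distinct(.data$species, .data$mirna_id) |>
      anti_join(meta, by = c("species", "mirna_id"))
    if (nrow(miss) > 0) {
      out <- bind_rows(out, mutate(miss, table = nm, .before = 1))
    }
  }
  out
}

#' @export
print.mirna_snapshot <- function(x, ...) {
  cat(sprintf("<mirna_snapshot> %s (version: %s)\n", x$root, x$version_tag))
  for (nm in names(x$tables)) {
    if (nm == "orthologs_bidir") next
    cat(sprintf("  %-20s %6d rows\n", nm, nrow(x$tables[[nm]])))
  }
  if (length(x$absent) > 0) {
    cat("  absent:", paste(x$absent, collapse = ", "), "\n")
  }
  if (nrow(x$dangling) > 0) {
    cat(sprintf("  %d dangling miRNA reference(s)\n", nrow(x$dangling)))
  }
  invisible(x)
}

#' Validate a loaded snapshot
#'
#' Produces a deterministic per-table report: row count, count of exactly
#' duplicated rows, and count of dangling miRNA references (targets tables
#' only). Reporting only — never fails.
#'
#' @param s A `mirna_snapshot` from [load_snapshot()].
#' @return A tibble with columns `table`, `present`, `n_rows`,
#'   `n_duplicate_rows`, `n_dangling_refs`.
#' @export
validate_snapshot <- function(s) {
  stopifnot(inherits(s, "mirna_snapshot"))
  dang <- count(s$dangling, .data$table, name = "n_dangling_refs")
  rows <- map(snapshot_table_names(), function(nm) {
    tbl <- s$tables[[nm]]
    if (is.null(tbl)) {
      tibble(table = nm, present = FALSE, n_rows = NA_integer_,
             n_duplicate_rows = NA_integer_, n_dangling_refs = NA_integer_)
    } else {
      nd <- dang$n_dangling_refs[match(nm, dang$table)]
      tibble(table = nm, present = TRUE, n_rows = nrow(tbl),
             n_duplicate_rows = sum(duplicated(tbl)),
             n_dangling_refs = if (grepl("^targets_", nm)) {
               if (is.na(nd)) 0L else as.integer(nd)
             } else 0L)
    }
  })
  bind_rows(rows)
}
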