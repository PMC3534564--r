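# Identifier cross-referencing within a species and ortholog mapping across
# species. Gene symbols are matched case-insensitively (zebrafish symbols are
# lowercase, human uppercase); every other namespace is matched exactly.
# One-to-many mappings expand to one row per value so downstream merges work
# on atomic keys.

#' Cross-reference identifiers between namespaces
#'
#' Maps a set of identifiers from one namespace to another within a species,
#' through the snapshot's cross-reference table. Duplicated inputs are
#' collapsed before the query; input order is preserved in the output; an
#' input with several distinct target values yields several rows; an unmapped
#' input appears once with `matched = FALSE` and `NA` output.
#'
#' @param ids Character vector of identifiers (may be empty).
#' @param from_ns,to_ns Source and target namespaces (see [id_namespaces()]);
#'   must differ.
#' @param species A species code.
#' @param snapshot A `mirna_snapshot`.
#' @param max_rows Retrieval cap (default [retrieval_cap()]).
#' @return A tibble with columns `input_id`, `output_id`, `matched`.
#' @export
xref <- function(ids, from_ns, to_ns, species, snapshot,
                 max_rows = retrieval_cap()) {
  assert_namespace(from_ns, "from_ns")
  assert_namespace(to_ns, "to_ns")
  if (from_ns == to_ns) abort("`from_ns` and `to_ns` must differ")
  assert_species(species)
  stopifnot(inherits(snapshot, "mirna_snapshot"))
  xr <- snapshot$tables$xref
  if (is.null(xr)) abort("snapshot has no xref table")

  empty <- tibble(input_id = character(0), output_id = character(0),
                  matched = logical(0))
  if (length(ids) == 0) return(empty)

  ids <- as.character(ids)
  uniq <- ids[!duplicated(ids)]
  n_collapsed <- length(ids) - length(uniq)
  if (n_collapsed > 0) {
    inform(sprintf("collapsed %d duplicated input id(s) before query", n_collapsed))
  }

  xr <- filter(xr, .data$species == !!species)
  from_rows <- filter(xr, .data$namespace == from_ns)
  to_rows <- filter(xr, .data$namespace == to_ns)

  # gene_symbol matches case-insensitively; values returned verbatim.
  from_key <- if (from_ns == "gene_symbol") tolower(from_rows$value) else from_rows$value
  query_key <- if (from_ns == "gene_symbol") tolower(uniq) else uniq

  hits <- tibble(input_id = uniq, .key = query_key) |>
    inner_join(tibble(.key = from_key, gene_key = from_rows$gene_key),
               by = ".key", relationship = "many-to-many") |>
    inner_join(select(to_rows, "gene_key", output_id = "value"),
               by = "gene_key", relationship = "many-to-many") |>
    distinct(.data$input_id, .data$output_id) |>
    mutate(matched = TRUE)

  out <- tibble(input_id = uniq) |>
    left_join(hits, by = "input_id") |>
    mutate(matched = !is.na(.data$matched)) |>
    arrange(match(.data$input_id, uniq), .data$output_id)
  out <- apply_retrieval_cap(out, max_rows)
  attr(out, "n_duplicates_collapsed") <- n_collapsed
  out
}

#' Map Ensembl genes to their orthologs in another species
#'
#' Returns every stored ortholog pair whose source side matches a queried
#' Ensembl gene id, with percent identity in both directions. The stored
#' table is directional but materialized in both directions at load time, so
#' either orientation of a pair is found. A queried gene with no ortholog
#' appears once with an `NA` partner.
#'
#' @param genes Character vector of Ensembl gene ids in species `src`.
#' @param src,dst Distinct species codes.
#' @param snapshot A `mirna_snapshot` whose ortholog table covers the pair.
#' @return A tibble with columns `src_ensembl_gene`, `dst_ensembl_gene`,
#'   `pct_identity_src`, `pct_identity_dst`, `matched`.
#' @export
map_orthologs <- function(genes, src, dst, snapshot) {
  assert_species(src, "src")
  assert_species(dst, "dst")
  if (src == dst) abort("`src` and `dst` must differ")
  stopifnot(inherits(snapshot, "mirna_snapshot"))
  orth <- snapshot$tables$orthologs_bidir
  if (is.null(orth)) abort("snapshot has no orthologs table")
  pool <- filter(orth, .data$src_species == src, .data$dst_species == dst)
  if (nrow(pool) == 0) {
    abort(sprintf("snapshot holds no ortholog data for species pair %s -> %s", src, dst))
  }
  empty <- tibble(src_ensembl_gene = character(0), dst_ensembl_gene = character(0),
                  pct_identity_src = numeric(0), pct_identity_dst = numeric(0),
                  matched = logical(0))
  if (length(genes) == 0) return(empty)
  genes <- as.character(genes)
  uniq <- genes[!duplicated(genes)]

  hits <- pool |>
    filter(.data$src_ensembl_gene %in% uniq) |>
    select("src_ensembl_gene", "dst_ensembl_gene",
           "pct_identity_src", "pct_identity_dst") |>
    distinct() |>
    mutate(matched = TRUE)
  tibble(src_ensembl_gene = uniq) |>
    left_join(hits, by = "src_ensembl_gene") |>
    mutate(matched = !is.na(.data$matched)) |>
    arrange(match(.data$src_ensembl_gene, uniq), .data$dst_ensembl_gene)
}
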