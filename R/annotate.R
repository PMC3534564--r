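# Batch annotation joins: GO / KEGG / gene cross-reference columns appended
# to an experiment table, either directly or through an ortholog bridge
# species. Multi-valued annotations are joined with "; " in term_id order so
# output is deterministic.

format_terms <- function(term_id, term_name) {
  ord <- order(term_id)
  paste(sprintf("%s (%s)", term_id[ord], term_name[ord]), collapse = "; ")
}

# Resolve an id column to gene symbols: tibble(.id, symbol). Non-symbol
# namespaces go through xref; unmapped ids keep an NA symbol.
resolve_symbols <- function(ids, id_type, species, snapshot) {
  uniq <- unique(as.character(ids))
  uniq <- uniq[!is.na(uniq)]
  if (id_type == "gene_symbol") {
    return(tibble(.id = uniq, symbol = uniq))
  }
  xr <- xref(uniq, id_type, "gene_symbol", species, snapshot)
  bind_rows(
    xr |> filter(.data$matched) |> select(.id = "input_id", symbol = "output_id"),
    tibble(.id = xr$input_id[!xr$matched], symbol = NA_character_))
}

annotation_table <- function(snapshot, source, species) {
  tbl_name <- switch(source, go = "annotations_go", kegg = "annotations_kegg",
                     abort(sprintf("unknown annotation source `%s`", source)))
  ann <- snapshot$tables[[tbl_name]]
  if (is.null(ann)) abort(sprintf("snapshot has no %s table", tbl_name))
  filter(ann, .data$species == !!species)
}

#' Annotate a table with GO terms, KEGG pathways or gene cross-references
#'
#' Joins annotations from the snapshot onto an experiment table, keyed by an
#' identifier column. With `source = "gene"` the function appends
#' cross-reference columns (symbol, Entrez, Ensembl gene) instead of terms.
#' The wide layout appends a single multi-valued column (terms joined with
#' `"; "` in term_id order); the long layout emits one row per (gene, term).
#' Re-running replaces the appended column rather than duplicating it.
#'
#' @param t A data frame.
#' @param id_column Column holding the gene identifiers.
#' @param id_type Namespace of `id_column` (default `gene_symbol`).
#' @param source `"go"`, `"kegg"` or `"gene"`.
#' @param species Species code.
#' @param snapshot A `mirna_snapshot`.
#' @param layout `"wide"` (default) or `"long"`; ignored for
#'   `source = "gene"`.
#' @return The annotated experiment table. Long layout adds `term_id`,
#'   `term_name`, `category` columns (NA for unannotated genes).
#' @export
annotate_genes <- function(t, id_column, id_type = "gene_symbol",
                           source = c("go", "kegg", "gene"), species, snapshot,
                           layout = c("wide", "long")) {
  source <- match.arg(source)
  layout <- match.arg(layout)
  assert_namespace(id_type, "id_type")
  assert_species(species)
  stopifnot(inherits(snapshot, "mirna_snapshot"))
  t <- as_experiment_table(t)
  if (!id_column %in% names(t)) {
    abort(sprintf("column `%s` does not exist", id_column))
  }

  if (source == "gene") {
    for (ns in c("gene_symbol", "entrez", "ensembl_gene")) {
      if (ns == id_type) next
      xr <- xref(unique(as.character(t[[id_column]])), id_type, ns, species, snapshot)
      collapsed <- xr |>
        filter(.data$matched) |>
        summarise(val = paste(sort(.data$output_id), collapse = "; "),
                  .by = "input_id")
      col <- paste0(ns, "_xref")
      t[[col]] <- collapsed$val[match(as.character(t[[id_column]]), collapsed$input_id)]
    }
    return(t)
  }

  ann <- annotation_table(snapshot, source, species)
  sym_map <- resolve_symbols(t[[id_column]], id_type, species, snapshot)
  terms <- sym_map |>
    filter(!is.na(.data$symbol)) |>
    mutate(.sym = tolower(.data$symbol)) |>
    inner_join(mutate(ann, .sym = tolower(.data$gene_symbol)),
               by = ".sym", relationship = "many-to-many") |>
    distinct(.data$.id, .data$term_id, .data$term_name, .data$category)

  if (layout == "wide") {
    cell <- terms |>
      summarise(val = format_terms(.data$term_id, .data$term_name), .by = ".id")
    col <- paste0(source, "_terms")
    t[[col]] <- cell$val[match(as.character(t[[id_column]]), cell$.id)]
    t
  } else {
    t |>
      mutate(.id = as.character(.data[[id_column]])) |>
      left_join(terms, by = ".id") |>
      select(-".id")
  }
}

#' Annotate through an ortholog bridge species
#'
#' For species with sparse annotation, maps each gene to its ortholog(s) in a
#' better-annotated bridge species, retrieves annotations there, and carries
#' them back keyed by the original identifier. A provenance column records
#' the bridge gene(s) used. Genes without an ortholog get `NA`.
#'
#' @param t A data frame.
#' @param id_column Column holding identifiers in species `src`.
#' @param id_type Namespace of `id_column` (default `gene_symbol`).
#' @param src Source species of the table.
#' @param bridge Bridge species whose annotations are retrieved.
#' @param source `"go"` or `"kegg"`.
#' @param snapshot A `mirna_snapshot` with an ortholog table covering
#'   `(src, bridge)`.
#' @param layout `"wide"` or `"long"`.
#' @return The annotated experiment table with a `bridge_gene` provenance
#'   column and, wide, a `<source>_terms_via_<bridge>` column.
#' @export
annotate_via_ortholog <- function(t, id_column, id_type = "gene_symbol",
                                  src, bridge, source = c("go", "kegg"),
                                  snapshot, layout = c("wide", "long")) {
  source <- match.arg(source)
  layout <- match.arg(layout)
  assert_species(src, "src")
  assert_species(bridge, "bridge")
  stopifnot(inherits(snapshot, "mirna_snapshot"))
  t <- as_experiment_table(t)
  if (!id_column %in% names(t)) abort(sprintf("column `%s` does not exist", id_column))

  ids <- unique(as.character(t[[id_column]]))
  ids <- ids[!is.na(ids)]
  # src id -> src ensembl gene
  ens_map <- if (id_type == "ensembl_gene") {
    tibble(.id = ids, src_gene = ids)
  } else {
    xref(ids, id_type, "ensembl_gene", src, snapshot) |>
      filter(.data$matched) |>
      select(.id = "input_id", src_gene = "output_id")
  }
  orth <- map_orthologs(unique(ens_map$src_gene), src, bridge, snapshot) |>
    filter(.data$matched) |>
    select(src_gene = "src_ensembl_gene", bridge_gene = "dst_ensembl_gene")
  bridge_sym <- xref(unique(orth$bridge_gene), "ensembl_gene", "gene_symbol",
                     bridge, snapshot) |>
    filter(.data$matched) |>
    select(bridge_gene = "input_id", bridge_symbol = "output_id")
  chain <- ens_map |>
    inner_join(orth, by = "src_gene", relationship = "many-to-many") |>
    inner_join(bridge_sym, by = "bridge_gene", relationship = "many-to-many")

  ann <- annotation_table(snapshot, source, bridge)
  terms <- chain |>
    mutate(.sym = tolower(.data$bridge_symbol)) |>
    inner_join(mutate(ann, .sym = tolower(.data$gene_symbol)),
               by = ".sym", relationship = "many-to-many") |>
    distinct(.data$.id, .data$bridge_gene, .data$term_id, .data$term_name,
             .data$category)

  prov <- chain |>
    summarise(bridge_gene = paste(sort(unique(.data$bridge_gene)), collapse = "; "),
              .by = ".id")
  t$bridge_gene <- prov$bridge_gene[match(as.character(t[[id_column]]), prov$.id)]

  if (layout == "wide") {
    cell <- terms |>
      summarise(val = format_terms(.data$term_id, .data$term_name), .by = ".id")
    col <- sprintf("%s_terms_via_%s", source, bridge)
    t[[col]] <- cell$val[match(as.character(t[[id_column]]), cell$.id)]
    t
  } else {
    t |>
      mutate(.id = as.character(.data[[id_column]])) |>
      left_join(select(terms, -"bridge_gene"), by = ".id") |>
      select(-".id")
  }
}

#' Write gene sets to a GMT file
#'
#' Standard GMT: one set per line — set id, description, then members,
#' tab-separated.
#'
#' @param sets A long tibble with columns `term_id`, `term_name`,
#'   `gene_symbol`, or a [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set_collection")) {
    lines <- map_chr(names(sets$sets), function(id) {
      paste(c(id, sets$term_names[[id]] %||% id, sets$sets[[id]]), collapse = "\t")
    })
  } else {
    sets <- as_tibble(sets)
    grouped <- sets |>
      summarise(members = list(sort(unique(.data$gene_symbol))),
                .by = c("term_id", "term_name"))
    lines <- pmap(grouped, function(term_id, term_name, members) {
      paste(c(term_id, term_name, members), collapse = "\t")
    })
    lines <- unlist(lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT file
#'
#' @param path Path to a GMT file.
#' @return A long tibble with columns `term_id`, `term_name`, `gene_symbol`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- map(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) return(NULL)
    tibble(term_id = parts[1], term_name = parts[2], gene_symbol = parts[-(1:2)])
  })
  bind_rows(compact(rows))
}
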