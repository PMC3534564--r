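# The three-step integration pipeline wired end-to-end:
#   (1) cross-species homology filtering + consensus target prediction,
#   (2) multi-level merge of the target list with the mRNA experiment table,
#   (3) gene-set enrichment and hierarchical clustering of the merged rows.
# Every artifact is written with a provenance header; re-running with the
# same config and snapshot reproduces byte-identical outputs except the
# timestamp line.

#' Configure an integration workflow run
#'
#' @param snapshot_dir Snapshot directory (see [load_snapshot()]).
#' @param mirna_table Path to the significant-miRNA TSV (needs a `mirna_id`
#'   column; fold-change columns named `fc_*` are used by the optional
#'   anti-correlation filter).
#' @param mrna_table Path to the significant-mRNA TSV (needs `gene_symbol`;
#'   `entrez_id` and `fc_*` columns are used when present).
#' @param species Species of the experiment tables.
#' @param bridge_species Optional species whose target predictions are used
#'   after mapping the miRNAs through the seed-preserving homology filter
#'   (e.g. query human predictions for a zebrafish experiment). `NULL`
#'   queries `species` directly.
#' @param sources Prediction sources to consult.
#' @param min_agreement Consensus threshold.
#' @param level Consensus level, `"gene"` or `"pair"`.
#' @param max_mismatch Homology filter mismatch budget (default 1).
#' @param merge_mode `"intersection"` or `"union"`.
#' @param anti_correlated If `TRUE`, keep only merged rows where at least one
#'   regulating significant miRNA changes in the direction opposite to the
#'   mRNA (sign of the mean fold change across timepoints). Default `FALSE`.
#' @param go_category GO category for enrichment (default `"BP"`).
#' @param alpha Enrichment significance level.
#' @param background Optional character vector of background gene symbols;
#'   default: every gene symbol the snapshot knows for the annotation
#'   species (the array universe).
#' @param out_dir Output directory for the artifacts.
#' @return A `workflow_config` object.
#' @export
workflow_config <- function(snapshot_dir, mirna_table, mrna_table,
                            species = "dre", bridge_species = "hsa",
                            sources = target_sources(), min_agreement = 2L,
                            level = "gene", max_mismatch = 1L,
                            merge_mode = "intersection",
                            anti_correlated = FALSE, go_category = "BP",
                            alpha = 0.05, background = NULL, out_dir) {
  assert_species(species)
  if (!is.null(bridge_species)) assert_species(bridge_species, "bridge_species")
  sources <- assert_sources(sources)
  for (p in c(mirna_table, mrna_table)) {
    if (!file.exists(p)) abort(sprintf("input file `%s` does not exist", p))
  }
  if (!dir.exists(snapshot_dir)) abort(sprintf("snapshot directory `%s` does not exist", snapshot_dir))
  structure(list(snapshot_dir = snapshot_dir, mirna_table = mirna_table,
                 mrna_table = mrna_table, species = species,
                 bridge_species = bridge_species, sources = sources,
                 min_agreement = as.integer(min_agreement), level = level,
                 max_mismatch = as.integer(max_mismatch),
                 merge_mode = merge_mode,
                 anti_correlated = isTRUE(anti_correlated),
                 go_category = go_category, alpha = alpha,
                 background = background, out_dir = out_dir),
            class = "workflow_config")
}

# Strip the species prefix of a miRBase-style name: "dre-miR-21" -> "miR-21".
mirna_stem <- function(id) {
  sub("^[a-z]{3}-", "", id)
}

write_artifact <- function(tbl, path, provenance) {
  body <- readr::format_tsv(tbl, na = "NA")
  writeLines(c(provenance, sub("\n$", "", body)), path)
  invisible(path)
}

#' Run the three-step integration workflow
#'
#' Step 1 retrieves consensus targets for the experiment's miRNAs, optionally
#' after mapping them to a bridge species and filtering candidate homolog
#' pairs through the seed-preserving homology filter. Step 2 merges the
#' target list with the mRNA table through the default cascade (gene symbol,
#' then Entrez, then Entrez translated to previously unmapped gene symbols).
#' Step 3 runs hypergeometric GO enrichment on the merged gene list and
#' centroid-linkage clustering on its fold-change columns. All artifacts are
#' written to `cfg$out_dir` with provenance headers. An empty miRNA table
#' propagates to empty outputs at every stage with a warning, not an error.
#'
#' @param cfg A [workflow_config()].
#' @return A `workflow_result`: list with `targets`, `merged`, `report`,
#'   `enrichment`, `dendrogram`, `homology`, `log` and `paths`.
#' @export
run_workflow <- function(cfg) {
  stopifnot(inherits(cfg, "workflow_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    invisible(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("workflow stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  snapshot <- stage("load", load_snapshot(cfg$snapshot_dir))
  mirna_tbl <- stage("load", load_experiment_table(cfg$mirna_table))
  mrna_tbl <- stage("load", load_experiment_table(cfg$mrna_table))
  note("snapshot version %s", snapshot$version_tag)
  note("inputs: %d miRNA rows, %d mRNA rows", nrow(mirna_tbl), nrow(mrna_tbl))

  # Hash only the semantic parameters (not file locations) so relocating a
  # snapshot or output directory does not change the provenance hash; the
  # snapshot itself is identified by its version tag.
  cfg_for_hash <- c(cfg[setdiff(names(cfg), c("out_dir", "snapshot_dir",
                                              "mirna_table", "mrna_table"))],
                    list(snapshot_version = snapshot$version_tag))
  provenance <- c(sprintf("# config_hash: %s", rlang::hash(cfg_for_hash)),
                  sprintf("# snapshot_version: %s", snapshot$version_tag),
                  sprintf("# timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))

  empty_run <- nrow(mirna_tbl) == 0
  if (empty_run) warn("miRNA table is empty; all stages produce empty outputs")

  ## ---- Step 1: homology filter + consensus targets ---------------------
  homology <- NULL
  if (!empty_run && !is.null(cfg$bridge_species)) {
    homology <- stage("homology_filter", {
      meta_src <- get_metadata(mirna_tbl$mirna_id, cfg$species, snapshot)
      meta_bridge <- snapshot$tables$mirna_metadata |>
        filter(.data$species == cfg$bridge_species)
      cand <- meta_src |>
        filter(.data$matched) |>
        mutate(stem = mirna_stem(.data$mirna_id)) |>
        inner_join(meta_bridge |>
                     mutate(stem = mirna_stem(.data$mirna_id)) |>
                     select("stem", id_b = "mirna_id", seq_b = "mature_sequence"),
                   by = "stem", relationship = "many-to-many") |>
        select(id_a = "mirna_id", seq_a = "mature_sequence", "id_b", "seq_b")
      no_homolog <- setdiff(meta_src$mirna_id[meta_src$matched], cand$id_a)
      note("homology: %d of %d miRNAs have a %s homolog candidate (%d without)",
           length(unique(cand$id_a)), nrow(meta_src), cfg$bridge_species,
           length(no_homolog))
      hf <- homology_filter(cand, max_mismatch = cfg$max_mismatch)
      multi <- hf |> filter(.data$pass) |> count(.data$id_a) |> filter(.data$n > 1)
      if (nrow(multi) > 0) {
        note("homology: %d miRNA(s) keep multiple passing homologs", nrow(multi))
      }
      note("homology: %d of %d candidate pairs pass (<=%d mismatch, seed identical); %d query miRNAs",
           sum(hf$pass), nrow(hf), cfg$max_mismatch, length(unique(hf$id_b[hf$pass])))
      hf
    })
    query_ids <- unique(homology$id_b[homology$pass])
    query_species <- cfg$bridge_species
  } else {
    query_ids <- unique(mirna_tbl$mirna_id)
    query_species <- cfg$species
  }

  targets <- stage("predict_targets", {
    predict_targets(query_ids, query_species, cfg$sources, cfg$min_agreement,
                    cfg$level, snapshot)
  })
  note("step 1: %d consensus rows at level=%s, min_agreement=%d",
       nrow(targets), cfg$level, cfg$min_agreement)

  # Attach an Entrez column so the default multi-level plan has a second key.
  targets_merge <- as_tibble(targets)
  if (nrow(targets_merge) > 0) {
    ent <- xref(unique(targets_merge$gene_symbol), "gene_symbol", "entrez",
                query_species, snapshot) |>
      filter(.data$matched) |>
      summarise(entrez_id = min(.data$output_id), .by = "input_id")
    targets_merge <- left_join(targets_merge, ent,
                               by = c(gene_symbol = "input_id"))
  } else {
    targets_merge$entrez_id <- character(0)
  }

  ## ---- Step 2: multi-level merge ---------------------------------------
  plan <- merge_plan(
    merge_relation("gene_symbol", "gene_symbol", case_insensitive = TRUE),
    merge_relation("entrez_id", "entrez_id"),
    merge_relation("entrez_id", "gene_symbol",
                   translate_from = "entrez", translate_to = "gene_symbol",
                   species = query_species),
    mode = cfg$merge_mode)
  merge_res <- stage("merge_datasets",
                     merge_datasets(targets_merge, mrna_tbl, plan, snapshot))
  merged <- merge_res$merged
  report <- merge_res$report
  note("step 2: matched_total %d (levels: %s); left_unmatched %d; right_unmatched %d",
       report$matched_total, paste(report$levels$matched, collapse = "/"),
       report$left_unmatched, report$right_unmatched)

  if (cfg$anti_correlated && nrow(merged) > 0) {
    merged <- stage("anti_correlation", {
      filter_anti_correlated(merged, mirna_tbl, homology, query_ids,
                             query_species, cfg, snapshot, note)
    })
    note("step 2: %d rows remain after anti-correlation filter", nrow(merged))
  }

  ## ---- Step 3: enrichment + clustering ---------------------------------
  ann_species <- cfg$bridge_species %||% cfg$species
  sym_col <- if ("gene_symbol_right" %in% names(merged)) "gene_symbol_right"
             else "gene_symbol"
  matched_genes <- if (nrow(merged) > 0) {
    unique(stats::na.omit(
      dplyr::coalesce(toupper(merged[[sym_col]]),
                      toupper(merged[["gene_symbol_left"]] %||%
                                merged[[sym_col]]))))
  } else character(0)

  enrichment <- stage("enrich", {
    ann <- snapshot$tables$annotations_go
    if (is.null(ann)) abort("snapshot has no annotations_go table")
    ann <- ann |>
      filter(.data$species == ann_species, .data$category == cfg$go_category)
    universe <- cfg$background %||% {
      xr <- snapshot$tables$xref
      unique(xr$value[xr$species == ann_species & xr$namespace == "gene_symbol"])
    }
    if (length(matched_genes) == 0) {
      note("step 3: empty merged gene list; skipping enrichment")
      structure(tibble(term_id = character(0), term_name = character(0),
                       N = integer(0), K = integer(0), n = integer(0),
                       k = integer(0), p_value = numeric(0),
                       q_value = numeric(0), significant = logical(0),
                       significant_fdr = logical(0)),
                class = c("enrichment_result", "tbl_df", "tbl", "data.frame"),
                alpha = cfg$alpha, n_query = 0L, n_dropped = 0L)
    } else {
      gsc <- gene_set_collection(
        select(ann, "term_id", "term_name", "gene_symbol"), universe)
      enrich(matched_genes, gsc, alpha = cfg$alpha)
    }
  })
  note("step 3: %d sets tested, %d significant at p<=%g",
       nrow(enrichment), sum(enrichment$significant), cfg$alpha)

  fc_cols <- grep("^fc_", names(merged), value = TRUE)
  dendro <- NULL
  if (nrow(merged) >= 2 && length(fc_cols) >= 1) {
    dendro <- stage("hcluster", {
      mat <- as.matrix(merged[fc_cols])
      rownames(mat) <- make.unique(as.character(merged[[sym_col]]))
      hcluster(mat)
    })
    note("step 3: clustered %d rows over %d expression columns (%d inversion(s))",
         nrow(merged), length(fc_cols), sum(dendro$merges$inversion))
  } else {
    note("step 3: fewer than 2 merged rows or no fc_ columns; skipping clustering")
  }

  ## ---- artifacts --------------------------------------------------------
  paths <- list(
    consensus_targets = file.path(cfg$out_dir, "consensus_targets.tsv"),
    merged = file.path(cfg$out_dir, "merged.tsv"),
    merge_report = file.path(cfg$out_dir, "merge_report.tsv"),
    enrichment = file.path(cfg$out_dir, "enrichment.tsv"),
    tree = file.path(cfg$out_dir, "tree.nwk"),
    log = file.path(cfg$out_dir, "run.log"))
  write_artifact(as_tibble(targets), paths$consensus_targets, provenance)
  write_artifact(merged, paths$merged, provenance)
  write_artifact(tidy(report), paths$merge_report, provenance)
  write_artifact(as_tibble(enrichment), paths$enrichment, provenance)
  if (!is.null(dendro)) write_newick(dendro, paths$tree) else writeLines(character(0), paths$tree)
  writeLines(c(provenance, log_lines), paths$log)

  structure(list(targets = targets, merged = merged, report = report,
                 enrichment = enrichment, dendrogram = dendro,
                 homology = homology, log = log_lines, paths = paths,
                 config = cfg),
            class = "workflow_result")
}

# Keep only merged rows with at least one regulating significant miRNA whose
# mean fold change opposes the mRNA's. Regulation is looked up at pair level
# on the same sources/threshold as the main consensus query.
filter_anti_correlated <- function(merged, mirna_tbl, homology, query_ids,
                                   query_species, cfg, snapshot, note) {
  fc_cols_m <- grep("^fc_", names(mirna_tbl), value = TRUE)
  fc_cols_g <- grep("^fc_", names(merged), value = TRUE)
  if (length(fc_cols_m) == 0 || length(fc_cols_g) == 0) {
    note("anti-correlation: no fc_ columns on one side; filter skipped")
    return(merged)
  }
  pair_targets <- predict_targets(query_ids, query_species, cfg$sources,
                                  cfg$min_agreement, "pair", snapshot)
  # Map bridge miRNA ids back to the experiment's miRNAs by name stem.
  mirna_dir <- mirna_tbl |>
    mutate(stem = mirna_stem(.data$mirna_id),
           dir_mirna = sign(rowMeans(across(all_of(fc_cols_m))))) |>
    select("stem", "dir_mirna")
  sym_col <- if ("gene_symbol_right" %in% names(merged)) "gene_symbol_right" else "gene_symbol"
  reg <- as_tibble(pair_targets) |>
    mutate(stem = mirna_stem(.data$mirna_id), .sym = tolower(.data$gene_symbol)) |>
    inner_join(mirna_dir, by = "stem", relationship = "many-to-many")
  gene_dir <- merged |>
    mutate(.sym = tolower(.data[[sym_col]]),
           dir_gene = sign(rowMeans(across(all_of(fc_cols_g)))))
  anti_ok <- reg |>
    inner_join(distinct(gene_dir, .data$.sym, .data$dir_gene),
               by = ".sym", relationship = "many-to-many") |>
    filter(.data$dir_mirna * .data$dir_gene < 0) |>
    distinct(.data$.sym)
  gene_dir |>
    filter(.data$.sym %in% anti_ok$.sym) |>
    select(-".sym", -"dir_gene")
}

#' @export
print.workflow_result <- function(x, ...) {
  cat("<workflow_result>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
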