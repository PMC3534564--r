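# Deterministic synthetic snapshot + experiment generator with a planted-fact
# ledger. Every fact the generator plants (conserved pairs, two-source pairs,
# background singles, miRNA homolog edits, ortholog pairs, per-gene term
# lists, the enriched term) is written to ledger.tsv so tests can recount it
# independently of the query modules.

#' Specification for a synthetic snapshot and experiment
#'
#' Collects every knob of the synthetic-data generator. The same spec plus the
#' same seed always produces byte-identical output files.
#'
#' @param seed Integer RNG seed; the sole source of randomness.
#' @param n_genes Number of genes in the shared universe. Each gene exists in
#'   both species of `species_pair` (lowercase symbol in the source species,
#'   uppercase in the destination, mirroring zebrafish/human conventions).
#' @param n_mirnas Number of miRNA families; each family has one mature miRNA
#'   per species, the destination copy carrying planted sequence edits.
#' @param species_pair Named character vector `c(src = , dst = )`; default
#'   zebrafish to human.
#' @param background_rate Per-source probability that a (miRNA, gene) pair is
#'   predicted by that source alone. Background pairs are guaranteed
#'   single-source: a candidate already present anywhere is skipped.
#' @param n_conserved_pairs Pairs planted into all three sources (destination
#'   species), each with a distinct gene.
#' @param n_two_source_pairs Pairs planted into exactly two sources (rotating
#'   over the three source pairs), each with a distinct gene not used by a
#'   conserved pair.
#' @param ortholog_fraction Fraction of genes given a src->dst ortholog row
#'   with bidirectional percent identity.
#' @param mean_terms_per_gene Poisson mean of background GO terms per gene in
#'   the destination species (the source species is annotated at 30% of this
#'   rate, emulating a poorly annotated model organism).
#' @param n_terms Number of GO terms. Term 1 is the planted enriched term: its
#'   members preferentially cover the planted target genes.
#' @param n_sig_mirnas Number of significant miRNAs the experiment emits.
#' @param n_sig_genes Number of significant mRNA rows the experiment emits.
#' @param target_enrichment Fraction of significant genes that are planted
#'   consensus targets of the significant miRNAs.
#' @param mismatch_profile Named integer vector distributing the `n_mirnas`
#'   cross-species mature-sequence pairs over categories `identical` (0
#'   edits), `mismatch_out_seed` (1 edit outside positions 2-8),
#'   `mismatch_in_seed` (1 edit inside the seed) and `multi_mismatch` (2 edits
#'   outside the seed). Must sum to `n_mirnas`. Only the first two categories
#'   survive a `max_mismatch = 1` seed-preserving homology filter.
#' @return A `fixture_spec` object (a validated list).
#' @export
#' @examples
#' sp <- fixture_spec(seed = 11, n_genes = 60, n_mirnas = 10,
#'                    mismatch_profile = c(identical = 6, mismatch_out_seed = 2,
#'                                         mismatch_in_seed = 1, multi_mismatch = 1))
fixture_spec <- function(seed = 11L,
                         n_genes = 300L,
                         n_mirnas = 42L,
                         species_pair = c(src = "dre", dst = "hsa"),
                         background_rate = 0.02,
                         n_conserved_pairs = 25L,
                         n_two_source_pairs = 30L,
                         ortholog_fraction = 0.8,
                         mean_terms_per_gene = 3,
                         n_terms = 40L,
                         n_sig_mirnas = 42L,
                         n_sig_genes = 100L,
                         target_enrichment = 0.4,
                         mismatch_profile = c(identical = 24L,
                                              mismatch_out_seed = 9L,
                                              mismatch_in_seed = 5L,
                                              multi_mismatch = 4L)) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_mirnas = as.integer(n_mirnas),
               species_pair = species_pair,
               background_rate = background_rate,
               n_conserved_pairs = as.integer(n_conserved_pairs),
               n_two_source_pairs = as.integer(n_two_source_pairs),
               ortholog_fraction = ortholog_fraction,
               mean_terms_per_gene = mean_terms_per_gene,
               n_terms = as.integer(n_terms),
               n_sig_mirnas = as.integer(n_sig_mirnas),
               n_sig_genes = as.integer(n_sig_genes),
               target_enrichment = target_enrichment,
               mismatch_profile = mismatch_profile)

  assert_species(spec$species_pair[["src"]], "species_pair['src']")
  assert_species(spec$species_pair[["dst"]], "species_pair['dst']")
  if (spec$species_pair[["src"]] == spec$species_pair[["dst"]]) {
    abort("species_pair must name two distinct species")
  }
  probs <- c(background_rate = spec$background_rate,
             ortholog_fraction = spec$ortholog_fraction,
             target_enrichment = spec$target_enrichment)
  if (any(probs < 0 | probs > 1)) {
    abort("background_rate, ortholog_fraction and target_enrichment must lie in [0, 1]")
  }
  counts <- c(spec$n_genes, spec$n_mirnas, spec$n_conserved_pairs,
              spec$n_two_source_pairs, spec$n_terms, spec$n_sig_mirnas,
              spec$n_sig_genes)
  if (any(counts < 0) || spec$n_genes < 1 || spec$n_mirnas < 1) {
    abort("counts must be non-negative (n_genes, n_mirnas at least 1)")
  }
  need <- c("identical", "mismatch_out_seed", "mismatch_in_seed", "multi_mismatch")
  if (!setequal(names(spec$mismatch_profile), need)) {
    abort(sprintf("mismatch_profile must have exactly the names: %s",
                  paste(need, collapse = ", ")))
  }
  spec$mismatch_profile <- as.integer(spec$mismatch_profile[need])
  names(spec$mismatch_profile) <- need
  if (sum(spec$mismatch_profile) != spec$n_mirnas) {
    abort("mismatch_profile must sum to n_mirnas")
  }
  if (spec$n_conserved_pairs + spec$n_two_source_pairs > spec$n_genes) {
    abort("n_conserved_pairs + n_two_source_pairs cannot exceed n_genes (planted genes are distinct)")
  }
  if (spec$n_sig_mirnas > spec$n_mirnas) abort("n_sig_mirnas cannot exceed n_mirnas")
  if (spec$n_sig_genes > spec$n_genes) abort("n_sig_genes cannot exceed n_genes")
  if (spec$mean_terms_per_gene < 0) abort("mean_terms_per_gene must be non-negative")
  structure(spec, class = "fixture_spec")
}

# Species-specific identifier builders for synthetic genes. Index i is the
# gene's position in the universe; symbols are shared modulo case.
gene_ids <- function(i, species, role = c("src", "dst")) {
  role <- match.arg(role)
  base <- sprintf("g%06d", i)
  if (role == "src") {
    list(symbol = base,
         entrez = sprintf("%d", 100000L + i),
         ensembl_gene = sprintf("ENSDARG%011d", i),
         ensembl_transcript = sprintf("ENSDART%011d", i),
         genbank = sprintf("NM_%06d", i),
         uniprot = sprintf("Q%05d", i))
  } else {
    list(symbol = toupper(base),
         entrez = sprintf("%d", 200000L + i),
         ensembl_gene = sprintf("ENSG%011d", i),
         ensembl_transcript = sprintf("ENST%011d", i),
         genbank = sprintf("NM_%06d", 500000L + i),
         uniprot = sprintf("P%05d", i))
  }
}

rna_bases <- c("A", "C", "G", "U")

random_mature_sequence <- function(len = 22L) {
  paste(sample(rna_bases, len, replace = TRUE), collapse = "")
}

# Apply the planted edit pattern of one mismatch-profile category to a
# sequence; returns list(seq, positions).
apply_planted_edits <- function(seq, category) {
  chars <- strsplit(seq, "")[[1]]
  out_seed <- c(1L, 9:length(chars))
  in_seed <- 2:8
  positions <- switch(category,
    identical = integer(0),
    mismatch_out_seed = sample(out_seed, 1L),
    mismatch_in_seed = sample(in_seed, 1L),
    multi_mismatch = sort(sample(out_seed, 2L))
  )
  for (p in positions) {
    chars[p] <- sample(setdiff(rna_bases, chars[p]), 1L)
  }
  list(seq = paste(chars, collapse = ""), positions = positions)
}

ledger_row <- function(fact, k1 = NA, k2 = NA, v1 = NA, v2 = NA, v3 = NA) {
  tibble(fact = fact, k1 = as.character(k1), k2 = as.character(k2),
         v1 = as.character(v1), v2 = as.character(v2), v3 = as.character(v3))
}

#' Generate a synthetic reference snapshot
#'
#' Writes a full snapshot directory (manifest, eight reference tables,
#' version tag) plus a `ledger.tsv` recording every planted fact, so that any
#' downstream query result can be recounted independently. Generation is a
#' pure function of `(spec, spec$seed)`: the same call twice produces
#' byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a `snapshot_fixture` list with `path`, `ledger` (tibble)
#'   and `spec`.
#' @seealso [load_snapshot()], [generate_experiment()], [read_fixture_ledger()]
#' @export
generate_snapshot <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    abort(sprintf("output directory `%s` is not writable", out_dir))
  }
  src <- spec$species_pair[["src"]]
  dst <- spec$species_pair[["dst"]]

  res <- withr::with_seed(spec$seed, {
    n_g <- spec$n_genes
    n_m <- spec$n_mirnas
    ledger <- list()

    ## ---- miRNA metadata with planted cross-species edits --------------
    src_ids <- sprintf("%s-miR-%d", src, seq_len(n_m))
    dst_ids <- sprintf("%s-miR-%d", dst, seq_len(n_m))
    src_seqs <- vapply(seq_len(n_m), function(i) random_mature_sequence(22L), "")
    categories <- sample(rep(names(spec$mismatch_profile), spec$mismatch_profile))
    edits <- map(seq_len(n_m), function(i) apply_planted_edits(src_seqs[i], categories[i]))
    dst_seqs <- map_chr(edits, "seq")
    ledger <- c(ledger, list(ledger_row(
      "mirna_pair", src_ids, dst_ids, categories,
      map_chr(edits, function(e) paste(e$positions, collapse = ",")))))

    mirna_metadata <- bind_rows(
      tibble(species = src, mirna_id = src_ids,
             mature_accession = sprintf("MIMAT%07d", seq_len(n_m)),
             mature_sequence = src_seqs),
      tibble(species = dst, mirna_id = dst_ids,
             mature_accession = sprintf("MIMAT%07d", 100000L + seq_len(n_m)),
             mature_sequence = dst_seqs)
    )

    ## ---- planted target structure (destination species) ---------------
    sources <- target_sources()
    planted_gene_idx <- sample(n_g, spec$n_conserved_pairs + spec$n_two_source_pairs)
    conserved_gene_idx <- planted_gene_idx[seq_len(spec$n_conserved_pairs)]
    two_source_gene_idx <- planted_gene_idx[-seq_len(spec$n_conserved_pairs)]
    conserved_mirna_idx <- if (spec$n_conserved_pairs > 0) {
      sample(n_m, spec$n_conserved_pairs, replace = TRUE)
    } else integer(0)
    two_source_mirna_idx <- if (spec$n_two_source_pairs > 0) {
      sample(n_m, spec$n_two_source_pairs, replace = TRUE)
    } else integer(0)
    source_pairs <- list(c("targetscan", "microcosm"),
                         c("targetscan", "mirnaorg"),
                         c("microcosm", "mirnaorg"))
    two_source_assign <- if (spec$n_two_source_pairs > 0) {
      source_pairs[((seq_len(spec$n_two_source_pairs) - 1L) %% 3L) + 1L]
    } else list()

    dst_sym <- toupper(sprintf("g%06d", seq_len(n_g)))
    pair_key <- function(m, g) paste(m, g, sep = "|")
    membership <- setNames(vector("list", 3), sources)
    for (s in sources) membership[[s]] <- tibble(mirna = integer(0), gene = integer(0))

    for (j in seq_along(conserved_gene_idx)) {
      for (s in sources) {
        membership[[s]] <- add_row(membership[[s]],
                                   mirna = conserved_mirna_idx[j],
                                   gene = conserved_gene_idx[j])
      }
    }
    if (spec$n_conserved_pairs > 0) {
      ledger <- c(ledger, list(ledger_row(
        "conserved_pair", dst_ids[conserved_mirna_idx], dst_sym[conserved_gene_idx])))
    }
    for (j in seq_along(two_source_gene_idx)) {
      for (s in two_source_assign[[j]]) {
        membership[[s]] <- add_row(membership[[s]],
                                   mirna = two_source_mirna_idx[j],
                                   gene = two_source_gene_idx[j])
      }
    }
    if (spec$n_two_source_pairs > 0) {
      ledger <- c(ledger, list(ledger_row(
        "two_source_pair", dst_ids[two_source_mirna_idx], dst_sym[two_source_gene_idx],
        map_chr(two_source_assign, 1), map_chr(two_source_assign, 2))))
    }

    # Background singles: a candidate (miRNA, gene) already present anywhere
    # (planted or assigned to an earlier source) is skipped, so every
    # background pair is single-source by construction.
    used <- unique(unlist(lapply(membership, function(m) pair_key(m$mirna, m$gene))))
    for (s in sources) {
      hit <- which(runif(n_m * n_g) < spec$background_rate)
      if (length(hit) > 0) {
        m_idx <- ((hit - 1L) %% n_m) + 1L
        g_idx <- ((hit - 1L) %/% n_m) + 1L
        keys <- pair_key(m_idx, g_idx)
        keep <- !keys %in% used
        m_idx <- m_idx[keep]; g_idx <- g_idx[keep]
        used <- c(used, keys[keep])
        if (length(m_idx) > 0) {
          membership[[s]] <- add_row(membership[[s]], mirna = m_idx, gene = g_idx)
          ledger <- c(ledger, list(ledger_row(
            "background_pair", rep(s, length(m_idx)),
            dst_ids[m_idx], dst_sym[g_idx], rep(dst, length(m_idx)))))
        }
      }
    }

    make_target_table <- function(m_idx, g_idx, species, mirna_ids, role) {
      ids <- map(g_idx, gene_ids, species = species, role = role)
      tibble(species = species,
             mirna_id = mirna_ids[m_idx],
             gene_symbol = map_chr(ids, "symbol"),
             entrez_id = map_chr(ids, "entrez"),
             ensembl_transcript = map_chr(ids, "ensembl_transcript"))
    }
    targets <- map(sources, function(s) {
      m <- membership[[s]]
      make_target_table(m$mirna, m$gene, dst, dst_ids, "dst") |>
        arrange(.data$mirna_id, .data$gene_symbol)
    })
    names(targets) <- paste0("targets_", sources)

    # Zebrafish-capable source: microcosm additionally carries the source
    # species' own predictions — the conserved pairs mirrored into src
    # identifier space, plus src-space background singles.
    src_rows <- make_target_table(conserved_mirna_idx, conserved_gene_idx,
                                  src, src_ids, "src")
    hit <- which(runif(n_m * n_g) < spec$background_rate)
    if (length(hit) > 0) {
      m_idx <- ((hit - 1L) %% n_m) + 1L
      g_idx <- ((hit - 1L) %/% n_m) + 1L
      mirror <- pair_key(conserved_mirna_idx, conserved_gene_idx)
      keep <- !pair_key(m_idx, g_idx) %in% mirror
      m_idx <- m_idx[keep]; g_idx <- g_idx[keep]
      if (length(m_idx) > 0) {
        src_rows <- bind_rows(src_rows, make_target_table(m_idx, g_idx, src, src_ids, "src"))
        ledger <- c(ledger, list(ledger_row(
          "background_pair", rep("microcosm", length(m_idx)),
          src_ids[m_idx], tolower(dst_sym[g_idx]), rep(src, length(m_idx)))))
      }
    }
    src_rows <- arrange(src_rows, .data$mirna_id, .data$gene_symbol)
    targets$targets_microcosm <- bind_rows(targets$targets_microcosm, src_rows)

    ## ---- xref ----------------------------------------------------------
    xref_species <- function(species, role) {
      ids <- map(seq_len(n_g), gene_ids, species = species, role = role)
      key <- sprintf("%s:%06d", species, seq_len(n_g))
      bind_rows(map(id_namespaces(), function(ns) {
        field <- if (ns == "entrez") "entrez" else if (ns == "gene_symbol") "symbol" else ns
        tibble(species = species, gene_key = key, namespace = ns,
               value = map_chr(ids, field))
      }))
    }
    xref <- bind_rows(xref_species(src, "src"), xref_species(dst, "dst")) |>
      arrange(.data$species, .data$gene_key, .data$namespace)

    ## ---- orthologs -----------------------------------------------------
    n_orth <- round(spec$ortholog_fraction * n_g)
    orth_idx <- sort(sample(n_g, n_orth))
    orthologs <- tibble(
      src_species = src,
      src_ensembl_gene = map_chr(orth_idx, function(i) gene_ids(i, src, "src")$ensembl_gene),
      dst_species = dst,
      dst_ensembl_gene = map_chr(orth_idx, function(i) gene_ids(i, dst, "dst")$ensembl_gene),
      pct_identity_src = round(runif(n_orth, 50, 100), 1),
      pct_identity_dst = round(runif(n_orth, 50, 100), 1)
    )
    if (n_orth > 0) {
      ledger <- c(ledger, list(ledger_row(
        "ortholog", orthologs$src_ensembl_gene, orthologs$dst_ensembl_gene,
        format(orthologs$pct_identity_src, nsmall = 1),
        format(orthologs$pct_identity_dst, nsmall = 1))))
    }

    ## ---- annotations ---------------------------------------------------
    term_ids <- sprintf("GO:%07d", seq_len(spec$n_terms))
    term_names <- sprintf("process_%03d", seq_len(spec$n_terms))
    # Term 1 is always BP (it is the planted enriched term); the rest cycle.
    term_cat <- c("BP", rep(c("BP", "MF", "CC"), length.out = max(spec$n_terms - 1L, 0L)))

    # Planted enriched term: membership built to cover the planted consensus
    # target genes, so a target-enriched experiment query lights it up.
    m1_size <- max(min(n_g, 10L), round(0.12 * n_g))
    seed_members <- planted_gene_idx[seq_len(min(length(planted_gene_idx),
                                                 round(0.6 * length(planted_gene_idx))))]
    filler <- setdiff(seq_len(n_g), seed_members)
    extra <- if (m1_size > length(seed_members)) {
      sample(filler, min(length(filler), m1_size - length(seed_members)))
    } else integer(0)
    members1 <- sort(unique(c(seed_members, extra)))
    ledger <- c(ledger, list(
      ledger_row("enriched_term", term_ids[1], term_names[1], length(members1)),
      ledger_row("enriched_member", dst_sym[members1])))

    draw_terms <- function(rate) {
      map(seq_len(n_g), function(i) {
        k <- rpois(1, rate)
        if (k == 0 || spec$n_terms < 2) integer(0) else {
          sort(sample(2:spec$n_terms, min(k, spec$n_terms - 1L)))
        }
      })
    }
    build_go <- function(species, syms, per_gene, planted_idx) {
      rows <- imap(per_gene, function(terms, i) {
        if (length(terms) == 0) return(NULL)
        tibble(species = species, gene_symbol = syms[i],
               term_id = term_ids[terms], term_name = term_names[terms],
               category = term_cat[terms])
      })
      planted <- tibble(species = species, gene_symbol = syms[planted_idx],
                        term_id = term_ids[1], term_name = term_names[1],
                        category = "BP")
      bind_rows(compact(rows), planted) |>
        distinct() |>
        arrange(.data$gene_symbol, .data$term_id)
    }
    go_dst <- build_go(dst, dst_sym, draw_terms(spec$mean_terms_per_gene), members1)
    go_src <- build_go(src, tolower(dst_sym), draw_terms(0.3 * spec$mean_terms_per_gene),
                       members1)
    annotations_go <- bind_rows(go_dst, go_src)
    ledger <- c(ledger, list(ledger_row(
      "gene_term", annotations_go$species, annotations_go$gene_symbol,
      annotations_go$term_id)))

    n_path <- max(4L, spec$n_terms %/% 4L)
    path_ids <- sprintf("ko%05d", seq_len(n_path))
    path_names <- sprintf("pathway_%03d", seq_len(n_path))
    draw_paths <- function(rate) {
      map(seq_len(n_g), function(i) {
        k <- rpois(1, rate)
        if (k == 0) integer(0) else sort(sample(n_path, min(k, n_path)))
      })
    }
    build_kegg <- function(species, syms, per_gene) {
      rows <- imap(per_gene, function(ps, i) {
        if (length(ps) == 0) return(NULL)
        tibble(species = species, gene_symbol = syms[i],
               term_id = path_ids[ps], term_name = path_names[ps],
               category = "pathway")
      })
      bind_rows(compact(rows)) |> arrange(.data$gene_symbol, .data$term_id)
    }
    annotations_kegg <- bind_rows(build_kegg(dst, dst_sym, draw_paths(1)),
                                  build_kegg(src, tolower(dst_sym), draw_paths(0.5)))

    tables <- c(targets,
                list(mirna_metadata = mirna_metadata, xref = xref,
                     orthologs = orthologs, annotations_go = annotations_go,
                     annotations_kegg = annotations_kegg))
    list(tables = tables, ledger = ledger)
  })

  tables <- res$tables
  ledger <- c(res$ledger, list(ledger_row(
    "table_rows", names(tables), map_int(tables, nrow))))
  ledger <- bind_rows(ledger)

  manifest <- tibble(table_name = names(tables),
                     file_name = paste0(names(tables), ".tsv"))
  write_table_file(manifest, file.path(out_dir, "manifest.tsv"))
  for (nm in names(tables)) {
    write_table_file(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  writeLines(sprintf("synthetic-snapshot-seed%d", spec$seed),
             file.path(out_dir, "version.txt"))
  write_table_file(ledger, file.path(out_dir, "ledger.tsv"))

  invisible(structure(list(path = out_dir, ledger = ledger, spec = spec),
                      class = "snapshot_fixture"))
}

#' Read a fixture ledger
#'
#' @param dir A directory written by [generate_snapshot()] or
#'   [generate_experiment()].
#' @param which `"snapshot"` (ledger.tsv) or `"experiment"`
#'   (experiment_ledger.tsv).
#' @return A tibble of planted facts (`fact`, `k1`, `k2`, `v1`, `v2`, `v3`).
#' @export
read_fixture_ledger <- function(dir, which = c("snapshot", "experiment")) {
  which <- match.arg(which)
  fn <- if (which == "snapshot") "ledger.tsv" else "experiment_ledger.tsv"
  path <- file.path(dir, fn)
  if (!file.exists(path)) abort(sprintf("no %s in `%s`", fn, dir))
  read_table_file(path)
}

# Gene-level consensus (agreement >= 2) of a set of destination-species
# miRNAs, recomputed directly from the raw snapshot tables with base set
# operations. Used by the experiment generator so its ledger does not depend
# on predict_targets().
consensus_gene_recount <- function(snapshot_dir, query_mirnas, dst_species,
                                   min_agreement = 2L) {
  per_source <- map(target_sources(), function(s) {
    tbl <- read_table_file(file.path(snapshot_dir, paste0("targets_", s, ".tsv")))
    unique(tbl$gene_symbol[tbl$species == dst_species &
                             tbl$mirna_id %in% query_mirnas])
  })
  genes <- unique(unlist(per_source))
  counts <- vapply(genes, function(g) {
    sum(vapply(per_source, function(gs) g %in% gs, logical(1)))
  }, integer(1))
  sort(genes[counts >= min_agreement])
}

#' Generate a synthetic miRNA/mRNA experiment
#'
#' Emits the two significance tables of a miRNA + mRNA profiling experiment
#' (fold changes over three developmental timepoints, p-values below 0.05)
#' with planted, ledger-recorded structure: exactly
#' `round(target_enrichment * n_sig_genes)` mRNA rows are consensus
#' (agreement >= 2) targets of the significant miRNAs that survive the
#' seed-preserving homology filter, and those planted rows preferentially
#' carry the snapshot's planted enriched GO term.
#'
#' @param spec The same [fixture_spec()] used for the snapshot.
#' @param snapshot_dir Directory written by [generate_snapshot()] for `spec`.
#' @param out_dir Output directory for `mirna_experiment.tsv`,
#'   `mrna_experiment.tsv` and `experiment_ledger.tsv`.
#' @return Invisibly, a list with `mirna_table`, `mrna_table`, `ledger` and
#'   `path`.
#' @export
generate_experiment <- function(spec, snapshot_dir, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  snap_ledger <- read_fixture_ledger(snapshot_dir, "snapshot")
  pairs <- filter(snap_ledger, .data$fact == "mirna_pair")
  if (nrow(pairs) != spec$n_mirnas) {
    abort("snapshot_dir does not match spec: miRNA count differs")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  src <- spec$species_pair[["src"]]
  dst <- spec$species_pair[["dst"]]

  res <- withr::with_seed(spec$seed + 1L, {
    ledger <- list()
    sig_idx <- sort(sample(spec$n_mirnas, spec$n_sig_mirnas))
    sig_src <- pairs$k1[sig_idx]
    sig_dst <- pairs$k2[sig_idx]
    passing <- pairs$v1[sig_idx] %in% c("identical", "mismatch_out_seed")
    ledger <- c(ledger, list(ledger_row(
      "sig_mirna", sig_src, sig_dst, pairs$v1[sig_idx], passing)))

    consensus <- consensus_gene_recount(snapshot_dir, sig_dst[passing], dst)
    ledger <- c(ledger, list(ledger_row("consensus_gene", consensus)))

    n_plant <- round(spec$target_enrichment * spec$n_sig_genes)
    if (n_plant > length(consensus)) {
      abort(sprintf(paste0("spec/snapshot inconsistency: %d planted target genes ",
                           "requested but only %d consensus genes available"),
                    n_plant, length(consensus)))
    }
    enriched <- snap_ledger$k1[snap_ledger$fact == "enriched_member"]
    pref <- intersect(consensus, enriched)
    n_pref <- min(round(0.7 * n_plant), length(pref))
    planted <- character(0)
    if (n_plant > 0) {
      planted <- sample(pref, n_pref)
      rest_pool <- setdiff(consensus, planted)
      planted <- c(planted, sample(rest_pool, n_plant - n_pref))
    }
    all_dst_sym <- toupper(sprintf("g%06d", seq_len(spec$n_genes)))
    nontarget_pool <- setdiff(all_dst_sym, consensus)
    others <- sample(nontarget_pool, spec$n_sig_genes - n_plant)
    sig_genes <- sample(c(planted, others))  # shuffle row order
    ledger <- c(ledger, list(
      ledger_row("sig_gene", sig_genes, sig_genes %in% planted),
      ledger_row("expected_overlap", "n", n_plant),
      ledger_row("planted_term",
                 snap_ledger$k1[snap_ledger$fact == "enriched_term"][1])))

    gi <- match(sig_genes, all_dst_sym)
    mrna_table <- tibble(
      gene_symbol = tolower(sig_genes),
      entrez_id = sprintf("%d", 100000L + gi),
      p_value = round(runif(spec$n_sig_genes, 1e-4, 0.049), 6),
      fc_24hpf = round(rnorm(spec$n_sig_genes, 0, 1.2), 4),
      fc_48hpf = round(rnorm(spec$n_sig_genes, 0, 1.2), 4),
      fc_72hpf = round(rnorm(spec$n_sig_genes, 0, 1.2), 4)
    )
    mirna_table <- tibble(
      mirna_id = sig_src,
      p_value = round(runif(spec$n_sig_mirnas, 1e-4, 0.049), 6),
      fc_24hpf = round(rnorm(spec$n_sig_mirnas, 0, 1.5), 4),
      fc_48hpf = round(rnorm(spec$n_sig_mirnas, 0, 1.5), 4),
      fc_72hpf = round(rnorm(spec$n_sig_mirnas, 0, 1.5), 4)
    )
    list(mirna_table = mirna_table, mrna_table = mrna_table,
         ledger = bind_rows(ledger))
  })

  write_table_file(res$mirna_table, file.path(out_dir, "mirna_experiment.tsv"))
  write_table_file(res$mrna_table, file.path(out_dir, "mrna_experiment.tsv"))
  write_table_file(res$ledger, file.path(out_dir, "experiment_ledger.tsv"))
  invisible(list(mirna_table = res$mirna_table, mrna_table = res$mrna_table,
                 ledger = res$ledger, path = out_dir))
}
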