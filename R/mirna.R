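# miRNA retrievals: consensus target prediction across the three prediction
# sources, reverse lookup of regulating miRNAs, mature metadata, and the
# seed-preserving homology filter used to map miRNAs across species.

consensus_flag_cols <- c("in_targetscan", "in_microcosm", "in_mirnaorg")

#' Consensus miRNA target prediction
#'
#' Queries the selected prediction sources for the targets of a set of miRNAs
#' and keeps predictions supported by at least `min_agreement` sources. At
#' `level = "pair"` each row is a (miRNA, gene) pair with per-source
#' membership flags; at `level = "gene"` rows are unique genes and a gene's
#' flag for a source is true if *any* queried miRNA targets it there. Output
#' is sorted by agreement count (descending) then key, and obeys the
#' retrieval cap.
#'
#' @param mirnas Character vector of miRNA ids (miRBase-style names).
#' @param species Species code of the query.
#' @param sources Subset of [target_sources()] to consult.
#' @param min_agreement Minimum number of supporting sources, between 1 and
#'   `length(sources)`.
#' @param level `"gene"` (default) or `"pair"`.
#' @param snapshot A `mirna_snapshot`.
#' @param max_rows Retrieval cap.
#' @return A tibble of class `consensus_targets`: key column(s) (`mirna_id`
#'   and/or `gene_symbol`), the three `in_*` flags (always present;
#'   unselected sources are `FALSE`) and `agreement_count`.
#' @export
predict_targets <- function(mirnas, species, sources = target_sources(),
                            min_agreement = 2L, level = c("gene", "pair"),
                            snapshot, max_rows = retrieval_cap()) {
  level <- match.arg(level)
  assert_species(species)
  sources <- assert_sources(sources)
  stopifnot(inherits(snapshot, "mirna_snapshot"))
  if (min_agreement < 1 || min_agreement > length(sources)) {
    abort(sprintf("`min_agreement` must lie in 1..%d (the number of selected sources)",
                  length(sources)))
  }

  key_cols <- if (level == "pair") c("mirna_id", "gene_symbol") else "gene_symbol"
  empty <- bind_cols(
    as_tibble(setNames(rep(list(character(0)), length(key_cols)), key_cols)),
    as_tibble(setNames(rep(list(logical(0)), 3), consensus_flag_cols)),
    tibble(agreement_count = integer(0)))
  if (length(mirnas) == 0) {
    return(new_consensus_targets(empty, level, min_agreement, sources))
  }
  mirnas <- unique(as.character(mirnas))

  per_source <- map(sources, function(s) {
    tbl <- snapshot$tables[[paste0("targets_", s)]]
    if (is.null(tbl)) return(tibble(mirna_id = character(0), gene_symbol = character(0)))
    tbl |>
      filter(.data$species == !!species, .data$mirna_id %in% mirnas) |>
      distinct(.data$mirna_id, .data$gene_symbol)
  })
  names(per_source) <- sources
  supported <- map_lgl(per_source, function(t) nrow(t) > 0)
  species_rows <- map_lgl(sources, function(s) {
    tbl <- snapshot$tables[[paste0("targets_", s)]]
    !is.null(tbl) && any(tbl$species == species)
  })
  if (!any(species_rows)) {
    abort(sprintf("no selected source holds predictions for species `%s`", species))
  }

  seen <- unique(unlist(map(per_source, "mirna_id")))
  missing <- setdiff(mirnas, seen)
  if (length(missing) > 0) {
    for (m in missing) {
      warn(sprintf("miRNA `%s` is absent from every selected source for species `%s`",
                   m, species))
    }
  }

  long <- bind_rows(per_source, .id = "source")
  if (level == "gene") long <- distinct(long, .data$source, .data$gene_symbol)

  if (nrow(long) == 0) {
    return(new_consensus_targets(empty, level, min_agreement, sources))
  }
  wide <- long |>
    mutate(present = TRUE, source = paste0("in_", .data$source)) |>
    tidyr::pivot_wider(names_from = "source", values_from = "present",
                       values_fill = FALSE)
  for (fc in consensus_flag_cols) {
    if (!fc %in% names(wide)) wide[[fc]] <- FALSE
  }
  selected_flags <- paste0("in_", sources)
  wide <- wide |>
    mutate(agreement_count = rowSums(across(all_of(selected_flags)))) |>
    mutate(agreement_count = as.integer(.data$agreement_count)) |>
    filter(.data$agreement_count >= min_agreement) |>
    select(all_of(key_cols), all_of(consensus_flag_cols), "agreement_count") |>
    arrange(desc(.data$agreement_count), !!!rlang::syms(key_cols))

  wide <- apply_retrieval_cap(wide, max_rows)
  new_consensus_targets(wide, level, min_agreement, sources)
}

new_consensus_targets <- function(tbl, level, min_agreement, sources) {
  structure(tbl, class = c("consensus_targets", class(tbl)),
            level = level, min_agreement = min_agreement, sources = sources)
}

#' Find the miRNAs predicted to regulate a set of genes
#'
#' Reverse lookup: for each input gene, every (miRNA, source) prediction
#' naming it as a target. Non-symbol identifiers are first translated to gene
#' symbols via [xref()]; an untranslatable input yields a warning row rather
#' than an error. Genes with no predicted regulator appear once with `NA`.
#'
#' @param genes Character vector of gene identifiers.
#' @param id_type Namespace of `genes` (default `gene_symbol`).
#' @param species Species code.
#' @param sources Subset of [target_sources()].
#' @param snapshot A `mirna_snapshot`.
#' @return A tibble with columns `gene` (the input id as given), `mirna_id`,
#'   `source`.
#' @export
regulatory_mirnas <- function(genes, id_type = "gene_symbol", species,
                              sources = target_sources(), snapshot) {
  assert_namespace(id_type, "id_type")
  assert_species(species)
  sources <- assert_sources(sources)
  stopifnot(inherits(snapshot, "mirna_snapshot"))
  empty <- tibble(gene = character(0), mirna_id = character(0), source = character(0))
  if (length(genes) == 0) return(empty)
  genes <- as.character(genes)
  uniq <- genes[!duplicated(genes)]

  if (id_type == "gene_symbol") {
    sym_map <- tibble(gene = uniq, symbol = uniq)
  } else {
    xr <- xref(uniq, id_type, "gene_symbol", species, snapshot)
    unmapped <- xr$input_id[!xr$matched]
    for (u in unmapped) {
      warn(sprintf("input id `%s` (%s) could not be translated to a gene symbol", u, id_type))
    }
    sym_map <- xr |>
      filter(.data$matched) |>
      select(gene = "input_id", symbol = "output_id")
    sym_map <- bind_rows(sym_map, tibble(gene = unmapped, symbol = NA_character_))
  }

  long <- bind_rows(map(sources, function(s) {
    tbl <- snapshot$tables[[paste0("targets_", s)]]
    if (is.null(tbl)) return(NULL)
    tbl |>
      filter(.data$species == !!species) |>
      distinct(.data$mirna_id, .data$gene_symbol) |>
      mutate(source = s)
  }))

  hits <- sym_map |>
    filter(!is.na(.data$symbol)) |>
    mutate(.sym = tolower(.data$symbol)) |>
    inner_join(mutate(long, .sym = tolower(.data$gene_symbol)),
               by = ".sym", relationship = "many-to-many") |>
    distinct(.data$gene, .data$mirna_id, .data$source)

  out <- tibble(gene = uniq) |>
    left_join(hits, by = "gene") |>
    arrange(match(.data$gene, uniq), .data$mirna_id, .data$source)
  out
}

#' Retrieve mature miRNA metadata
#'
#' Looks up mature accession and sequence for each distinct input id.
#' Sequences are normalized to uppercase RNA (`T` to `U`). Unknown ids are
#' returned with `NA` fields and `matched = FALSE`. A known sequence whose
#' length falls outside 18-26 nt triggers a warning, not an error.
#'
#' @param mirnas Character vector of miRNA ids; duplicates collapse to one row.
#' @param species Species code.
#' @param snapshot A `mirna_snapshot` with a `mirna_metadata` table.
#' @return A tibble with columns `species`, `mirna_id`, `mature_accession`,
#'   `mature_sequence`, `matched`.
#' @export
get_metadata <- function(mirnas, species, snapshot) {
  assert_species(species)
  stopifnot(inherits(snapshot, "mirna_snapshot"))
  meta <- snapshot$tables$mirna_metadata
  if (is.null(meta)) abort("snapshot has no mirna_metadata table")
  meta <- filter(meta, .data$species == !!species)
  if (nrow(meta) == 0) {
    abort(sprintf("snapshot has no mirna_metadata rows for species `%s`", species))
  }
  empty <- tibble(species = character(0), mirna_id = character(0),
                  mature_accession = character(0), mature_sequence = character(0),
                  matched = logical(0))
  if (length(mirnas) == 0) return(empty)
  uniq <- as.character(mirnas)[!duplicated(as.character(mirnas))]

  out <- tibble(mirna_id = uniq) |>
    left_join(select(meta, "mirna_id", "mature_accession", "mature_sequence"),
              by = "mirna_id") |>
    mutate(species = !!species,
           matched = !is.na(.data$mature_sequence),
           mature_sequence = ifelse(.data$matched,
                                    normalize_rna(.data$mature_sequence),
                                    NA_character_)) |>
    select("species", "mirna_id", "mature_accession", "mature_sequence", "matched")
  lens <- nchar(out$mature_sequence[out$matched])
  if (any(lens < 18 | lens > 26)) {
    warn("some mature sequences have lengths outside the typical 18-26 nt range")
  }
  out
}

# Mismatch accounting for one pair of normalized mature sequences:
# 5'-aligned Hamming distance over the overlap plus the absolute length
# difference; the seed is positions 2-8 (1-based, 5'->3').
compare_mature_pair <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ov <- min(length(ca), length(cb))
  n_mm <- sum(ca[seq_len(ov)] != cb[seq_len(ov)]) + abs(length(ca) - length(cb))
  seed_ok <- ov >= 8 && all(ca[2:8] == cb[2:8])
  list(n_mismatch = as.integer(n_mm), overlap_length = as.integer(ov),
       seed_identical = seed_ok)
}

#' Seed-preserving homology filter for miRNA pairs
#'
#' Compares candidate cross-species homolog pairs of mature miRNA sequences.
#' For each pair it counts mismatches (5'-aligned Hamming distance over the
#' overlap, plus the length difference) and checks that the seed region
#' (positions 2-8 from the 5' end) is identical. A pair passes when
#' `n_mismatch <= max_mismatch` *and* the seed is identical — a single seed
#' mismatch fails the pair even when the total mismatch count is within
#' budget. Homologs are compared as sequences (identity), not hybridized as
#' miRNA:mRNA duplexes.
#'
#' @param pairs A data frame with columns `seq_a` and `seq_b` (mature
#'   sequences; DNA alphabet and lowercase are normalized). Optional id
#'   columns (e.g. `id_a`, `id_b`) are carried through and used in error
#'   messages.
#' @param max_mismatch Maximum tolerated mismatch count (default 1).
#' @return The input tibble with columns `n_mismatch`, `overlap_length`,
#'   `seed_identical` and `pass` appended.
#' @export
#' @examples
#' homology_filter(tibble::tibble(
#'   id_a = "dre-miR-1", seq_a = "UGGAAUGUAAAGAAGUAUGUAU",
#'   id_b = "hsa-miR-1", seq_b = "UGGAAUGUAAAGAAGUAUGUAU"))
homology_filter <- function(pairs, max_mismatch = 1L) {
  pairs <- as_tibble(pairs)
  if (!all(c("seq_a", "seq_b") %in% names(pairs))) {
    abort("`pairs` must have columns `seq_a` and `seq_b`")
  }
  if (max_mismatch < 0) abort("`max_mismatch` must be >= 0")
  if (any(is.na(pairs$seq_a) | is.na(pairs$seq_b) |
            !nzchar(pairs$seq_a) | !nzchar(pairs$seq_b))) {
    abort("both sequences must be non-empty in every pair")
  }
  a <- normalize_rna(pairs$seq_a)
  b <- normalize_rna(pairs$seq_b)
  labels_a <- if ("id_a" %in% names(pairs)) pairs$id_a else NULL
  labels_b <- if ("id_b" %in% names(pairs)) pairs$id_b else NULL
  check_rna_alphabet(a, labels_a)
  check_rna_alphabet(b, labels_b)
  lens <- c(nchar(a), nchar(b))
  if (any(lens < 18 | lens > 26)) {
    warn("some mature sequences have lengths outside the typical 18-26 nt range")
  }
  cmp <- map2(a, b, compare_mature_pair)
  pairs |>
    mutate(n_mismatch = map_int(cmp, "n_mismatch"),
           overlap_length = map_int(cmp, "overlap_length"),
           seed_identical = map_lgl(cmp, "seed_identical"),
           pass = .data$n_mismatch <= max_mismatch & .data$seed_identical)
}
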