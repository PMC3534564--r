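# Closed vocabularies shared across modules. These mirror the snapshot schema:
# every species-qualified record carries exactly one of the five supported
# species codes, identifier namespaces form a closed enumeration, and target
# predictions come from exactly three sources.

#' Supported species codes
#'
#' The five species the toolkit supports: human (`hsa`), mouse (`mmu`),
#' rat (`rno`), zebrafish (`dre`) and macaque (`mml`).
#'
#' @return A character vector of species codes.
#' @export
#' @examples
#' species_codes()
species_codes <- function() {
  c("hsa", "mmu", "rno", "dre", "mml")
}

#' Supported identifier namespaces
#'
#' Closed set of identifier namespaces used by [xref()] and the snapshot
#' cross-reference table. Gene symbols are matched case-insensitively; all
#' other namespaces are matched exactly.
#'
#' @return A character vector of namespace names.
#' @export
id_namespaces <- function() {
  c("gene_symbol", "entrez", "ensembl_gene", "ensembl_transcript",
    "genbank", "uniprot")
}

#' Target prediction sources
#'
#' The three miRNA target prediction sources a snapshot can hold.
#'
#' @return A character vector: `targetscan`, `microcosm`, `mirnaorg`.
#' @export
target_sources <- function() {
  c("targetscan", "microcosm", "mirnaorg")
}

# Names of the tables a snapshot directory may declare in its manifest.
snapshot_table_names <- function() {
  c("targets_targetscan", "targets_microcosm", "targets_mirnaorg",
    "mirna_metadata", "xref", "orthologs", "annotations_go",
    "annotations_kegg")
}

# Required columns per snapshot table.
snapshot_table_schema <- function() {
  target_cols <- c("species", "mirna_id", "gene_symbol", "entrez_id",
                   "ensembl_transcript")
  list(
    targets_targetscan = target_cols,
    targets_microcosm  = target_cols,
    targets_mirnaorg   = target_cols,
    mirna_metadata     = c("species", "mirna_id", "mature_accession",
                           "mature_sequence"),
    xref               = c("species", "gene_key", "namespace", "value"),
    orthologs          = c("src_species", "src_ensembl_gene", "dst_species",
                           "dst_ensembl_gene", "pct_identity_src",
                           "pct_identity_dst"),
    annotations_go     = c("species", "gene_symbol", "term_id", "term_name",
                           "category"),
    annotations_kegg   = c("species", "gene_symbol", "term_id", "term_name",
                           "category")
  )
}

assert_species <- function(species, arg = "species") {
  if (length(species) != 1 || !species %in% species_codes()) {
    abort(sprintf("`%s` must be one of: %s", arg,
                  paste(species_codes(), collapse = ", ")))
  }
  species
}

assert_namespace <- function(ns, arg = "namespace") {
  if (length(ns) != 1 || !ns %in% id_namespaces()) {
    abort(sprintf("unknown namespace `%s` for `%s`; must be one of: %s",
                  as.character(ns)[1], arg,
                  paste(id_namespaces(), collapse = ", ")))
  }
  ns
}

assert_sources <- function(sources) {
  if (length(sources) == 0 || !all(sources %in% target_sources())) {
    abort(sprintf("`sources` must be a non-empty subset of {%s}",
                  paste(target_sources(), collapse = ", ")))
  }
  unique(sources)
}
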