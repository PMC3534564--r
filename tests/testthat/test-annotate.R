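test_that("wide annotation joins terms sorted by id; unannotated genes get NA", {
  d <- make_tiny_snapshot(seed = 19)
  s <- load_snapshot(d)
  ann <- s$tables$annotations_go
  ann_hsa <- ann[ann$species == "hsa", ]
  g <- names(sort(table(ann_hsa$gene_symbol), decreasing = TRUE))[1]
  t <- tibble::tibble(gene = c(g, "GXXX"))
  out <- annotate_genes(t, "gene", source = "go", species = "hsa", snapshot = s)
  rows <- ann_hsa[ann_hsa$gene_symbol == g, ]
  rows <- rows[order(rows$term_id), ]
  expect_identical(out$go_terms[1],
                   paste(sprintf("%s (%s)", rows$term_id, rows$term_name),
                         collapse = "; "))
  expect_identical(out$go_terms[2], NA_character_)
  # idempotent: re-running replaces the column rather than duplicating
  again <- annotate_genes(out, "gene", source = "go", species = "hsa", snapshot = s)
  expect_identical(sum(names(again) == "go_terms"), 1L)
  expect_identical(again$go_terms, out$go_terms)
})

test_that("wide and long layouts carry identical (gene, term) pair sets", {
  d <- make_tiny_snapshot(seed = 29)
  s <- load_snapshot(d)
  genes <- sprintf("G%06d", 1:25)
  t <- tibble::tibble(gene = genes)
  wide <- annotate_genes(t, "gene", source = "go", species = "hsa", snapshot = s)
  long <- annotate_genes(t, "gene", source = "go", species = "hsa", snapshot = s,
                         layout = "long")
  wide_pairs <- unlist(purrr::imap(setNames(wide$go_terms, wide$gene), function(cell, g) {
    if (is.na(cell)) character(0) else {
      ids <- stringr::str_extract_all(cell, "GO:[0-9]{7}")[[1]]
      paste(g, ids)
    }
  }), use.names = FALSE)
  long_pairs <- paste(long$gene[!is.na(long$term_id)],
                      long$term_id[!is.na(long$term_id)])
  expect_setequal(long_pairs, wide_pairs)
  # long row count equals per-gene term counts from an independent grouping
  ann <- s$tables$annotations_go
  counts <- table(ann$gene_symbol[ann$species == "hsa" & ann$gene_symbol %in% genes])
  expected <- sum(counts) + sum(!genes %in% names(counts))
  expect_identical(nrow(long), as.integer(expected))
})

test_that("entrez-keyed annotation resolves through xref first", {
  d <- make_tiny_snapshot()
  s <- load_snapshot(d)
  t_sym <- tibble::tibble(id = "G000001")
  t_ent <- tibble::tibble(id = "200001")
  w1 <- annotate_genes(t_sym, "id", source = "go", species = "hsa", snapshot = s)
  w2 <- annotate_genes(t_ent, "id", id_type = "entrez", source = "go",
                       species = "hsa", snapshot = s)
  expect_identical(w2$go_terms, w1$go_terms)
})

test_that("ortholog-bridge annotation attaches the bridge species' terms", {
  d <- make_tiny_snapshot(seed = 37)
  s <- load_snapshot(d)
  led <- read_fixture_ledger(d)
  orth <- led[led$fact == "ortholog", ]
  # pick an orthologged gene whose human counterpart has GO terms
  ann_hsa <- s$tables$annotations_go |> dplyr::filter(.data$species == "hsa")
  idx <- as.integer(sub("ENSDARG0*", "", orth$k1))
  has_terms <- toupper(sprintf("g%06d", idx)) %in% ann_hsa$gene_symbol
  i <- which(has_terms)[1]
  dre_sym <- sprintf("g%06d", idx[i])
  t <- tibble::tibble(gene = dre_sym)
  out <- annotate_via_ortholog(t, "gene", src = "dre", bridge = "hsa",
                               source = "go", snapshot = s)
  expect_identical(out$bridge_gene, orth$k2[i])
  hsa_terms <- ann_hsa$term_id[ann_hsa$gene_symbol == toupper(dre_sym)]
  got_ids <- stringr::str_extract_all(out$go_terms_via_hsa, "GO:[0-9]{7}")[[1]]
  expect_setequal(got_ids, hsa_terms)
  # a gene without ortholog gets NA
  orphan_idx <- setdiff(1:60, idx)[1]
  t2 <- tibble::tibble(gene = sprintf("g%06d", orphan_idx))
  out2 <- annotate_via_ortholog(t2, "gene", src = "dre", bridge = "hsa",
                                source = "go", snapshot = s)
  expect_identical(out2$bridge_gene, NA_character_)
  expect_identical(out2$go_terms_via_hsa, NA_character_)
})

test_that("native plus bridge annotations union like an independent set union", {
  d <- make_tiny_snapshot(seed = 43)
  s <- load_snapshot(d)
  genes <- sprintf("g%06d", 1:30)
  t <- tibble::tibble(gene = genes)
  native <- annotate_genes(t, "gene", source = "go", species = "dre", snapshot = s)
  bridged <- annotate_via_ortholog(t, "gene", src = "dre", bridge = "hsa",
                                   source = "go", snapshot = s)
  pull_ids <- function(cell) {
    if (is.na(cell)) character(0) else stringr::str_extract_all(cell, "GO:[0-9]{7}")[[1]]
  }
  ann <- s$tables$annotations_go
  led <- read_fixture_ledger(d)
  orth <- led[led$fact == "ortholog", ]
  for (i in seq_along(genes)) {
    got <- union(pull_ids(native$go_terms[i]), pull_ids(bridged$go_terms_via_hsa[i]))
    nat <- ann$term_id[ann$species == "dre" & ann$gene_symbol == genes[i]]
    hsa_gene <- orth$k2[match(sprintf("ENSDARG%011d", i), orth$k1)]
    via <- if (is.na(hsa_gene)) character(0) else {
      ann$term_id[ann$species == "hsa" & ann$gene_symbol == toupper(genes[i])]
    }
    expect_setequal(got, union(nat, via))
  }
})

test_that("GMT files round-trip through write and read", {
  d <- make_tiny_snapshot()
  s <- load_snapshot(d)
  long <- s$tables$annotations_go |>
    dplyr::filter(.data$species == "hsa") |>
    dplyr::select("term_id", "term_name", "gene_symbol")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(long, path)
  back <- read_gmt(path)
  expect_setequal(paste(back$term_id, back$gene_symbol),
                  paste(long$term_id, long$gene_symbol))
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_gte(length(first), 3)
})
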