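left_demo <- function() {
  tibble::tibble(sym = c("TP53", NA), entrez = c("7157", "999"), val = c(1.2, 0.5))
}

test_that("hand-enumerated two-table merges come out exactly", {
  right <- tibble::tibble(sym = c("TP53", "BRCA2"), p = c(0.01, 0.2))
  res_i <- merge_datasets(left_demo(), right, merge_plan(merge_relation("sym")))
  expect_identical(nrow(res_i$merged), 1L)
  expect_identical(res_i$merged$sym_left, "TP53")
  expect_identical(res_i$report$matched_total, 1L)
  res_u <- merge_datasets(left_demo(), right,
                          merge_plan(merge_relation("sym"), mode = "union"))
  expect_identical(nrow(res_u$merged), 3L)
  expect_identical(sum(is.na(res_u$merged$p)), 1L)    # unmatched left row
  expect_identical(sum(is.na(res_u$merged$val)), 1L)  # unmatched right row
})

test_that("a second relation catches rows the first missed, counted at their level", {
  right <- tibble::tibble(sym = c("TP53", NA), entrez = c(NA, "999"), p = c(0.01, 0.2))
  plan <- merge_plan(merge_relation("sym"), merge_relation("entrez"))
  res <- merge_datasets(left_demo(), right, plan)
  expect_identical(res$report$levels$matched, c(1L, 1L))
  expect_identical(res$report$left_unmatched, 0L)
  expect_identical(res$report$matched_total, 2L)
  # a row matchable at both levels is counted only at the first
  right2 <- tibble::tibble(sym = c("TP53"), entrez = c("7157"), p = 0.3)
  res2 <- merge_datasets(left_demo()[1, ], right2, plan)
  expect_identical(res2$report$levels$matched, c(1L, 0L))
})

test_that("self-merge on a unique key preserves row count", {
  t <- tibble::tibble(key = letters[1:5], v = 1:5)
  res <- merge_datasets(t, t, merge_plan(merge_relation("key")))
  expect_identical(nrow(res$merged), 5L)
  expect_identical(res$report$levels$matched, 5L)
})

test_that("union row count is conserved on random tables", {
  withr::local_seed(11)
  for (i in 1:20) {
    nl <- sample(3:25, 1); nr <- sample(3:25, 1)
    left <- tibble::tibble(k1 = sample(letters[1:8], nl, TRUE),
                           k2 = sample(LETTERS[1:8], nl, TRUE), x = rnorm(nl))
    right <- tibble::tibble(k1 = sample(letters[1:8], nr, TRUE),
                            k2 = sample(LETTERS[1:8], nr, TRUE), y = rnorm(nr))
    plan_u <- merge_plan(merge_relation("k1"), merge_relation("k2"), mode = "union")
    plan_i <- merge_plan(merge_relation("k1"), merge_relation("k2"))
    u <- merge_datasets(left, right, plan_u)
    ix <- merge_datasets(left, right, plan_i)
    r <- u$report
    expect_identical(nrow(u$merged),
                     r$matched_rows + r$left_unmatched + r$right_unmatched)
    expect_identical(r$matched_total, sum(r$levels$matched))
    expect_identical(r$matched_total + r$left_unmatched, r$left_n)
    # intersection rows are a subset of union rows
    key_of <- function(m) do.call(paste, c(m[setdiff(names(m), ".merge_level")], sep = "\r"))
    expect_true(all(key_of(ix$merged) %in% key_of(u$merged)))
    # permuting right rows never changes the counts
    perm <- right[sample(nrow(right)), ]
    r2 <- merge_datasets(left, perm, plan_u)$report
    expect_identical(r2$levels$matched, r$levels$matched)
    expect_identical(r2$right_unmatched, r$right_unmatched)
  }
})

test_that("reversing independent relations preserves matched_total", {
  left <- tibble::tibble(a = c("x", "y", "z", NA), b = c(NA, "q", NA, "r"), v = 1:4)
  right <- tibble::tibble(a = c("x", NA, NA), b = c(NA, "q", "r"), w = 1:3)
  p12 <- merge_plan(merge_relation("a"), merge_relation("b"))
  p21 <- merge_plan(merge_relation("b"), merge_relation("a"))
  r12 <- merge_datasets(left, right, p12)$report
  r21 <- merge_datasets(left, right, p21)$report
  expect_identical(r12$matched_total, r21$matched_total)
})

test_that("translated relations map the left key through the snapshot", {
  d <- make_tiny_snapshot()
  s <- load_snapshot(d)
  left <- tibble::tibble(entrez = c("100001", "100002"), stat = c(1, 2))
  right <- tibble::tibble(gene_symbol = c("G000001", "other"), p = c(0.1, 0.2))
  plan <- merge_plan(merge_relation("entrez", "gene_symbol",
                                    translate_from = "entrez",
                                    translate_to = "gene_symbol", species = "dre"))
  res <- merge_datasets(left, right, plan, snapshot = s)
  # dre entrez 100001 translates to symbol g000001, matching G000001 case-insensitively
  expect_identical(nrow(res$merged), 1L)
  expect_identical(res$merged$entrez, "100001")
  expect_error(merge_datasets(left, right, plan), "no snapshot")
})

test_that("one-to-many matches expand cartesian within key", {
  left <- tibble::tibble(k = "a", v = 1)
  right <- tibble::tibble(k = c("a", "a", "a"), w = 1:3)
  res <- merge_datasets(left, right, merge_plan(merge_relation("k")))
  expect_identical(nrow(res$merged), 3L)
  expect_identical(res$report$matched_total, 1L)
  expect_identical(res$report$matched_rows, 3L)
})

test_that("dedupe keeps the earliest row and counts removals like a grouping oracle", {
  t <- tibble::tibble(k = c("a", "b", "a", "c", "b", "a"), v = 1:6)
  expect_message(out <- dedupe_rows(t, "k"), "removed 3")
  expect_identical(out$v, c(1L, 2L, 4L))
  expect_identical(attr(out, "n_removed"), 3L)
  expect_error(dedupe_rows(t, character(0)), "at least one")
  # no duplicates: unchanged
  t2 <- tibble::tibble(k = letters[1:4], v = 1:4)
  expect_identical(dedupe_rows(t2, "k")$v, t2$v)
  # random tables vs an independent group-count oracle
  withr::local_seed(5)
  for (i in 1:10) {
    tt <- tibble::tibble(k = sample(letters[1:6], 30, TRUE), v = rnorm(30))
    expected_removed <- 30L - length(unique(tt$k))
    out <- suppressMessages(dedupe_rows(tt, "k"))
    expect_identical(attr(out, "n_removed"), expected_removed)
  }
})

test_that("split and merge of delimited columns round-trip", {
  t <- tibble::tibble(go = c("GO:1;GO:2", "GO:3", "GO:4;GO:5;GO:6"))
  sp <- split_column(t, "go", ";")
  expect_identical(sp$go_1, c("GO:1", "GO:3", "GO:4"))
  expect_identical(sp$go_2, c("GO:2", NA, "GO:5"))
  expect_identical(sp$go_3, c(NA, NA, "GO:6"))
  back <- merge_columns(sp, c("go_1", "go_2", "go_3"), ";", into = "go")
  expect_identical(back$go, t$go)
  expect_error(split_column(t, "go", ""), "non-empty")
  # NA-skip contract
  m <- merge_columns(tibble::tibble(a = "a", b = NA_character_, c = "c"),
                     c("a", "b", "c"), "_", into = "out")
  expect_identical(m$out, "a_c")
  # property: random NA-free delimited columns round-trip
  withr::local_seed(8)
  for (i in 1:10) {
    vals <- purrr::map_chr(1:12, function(j) {
      paste(sample(letters, sample(1:4, 1), TRUE), collapse = "|")
    })
    tt <- tibble::tibble(col = vals)
    spl <- split_column(tt, "col", "|")
    parts <- grep("^col_", names(spl), value = TRUE)
    rt <- merge_columns(spl, parts, "|", into = "col")
    expect_identical(rt$col, vals)
  }
})

test_that("identifier extraction presets match a character-scan oracle", {
  t <- tibble::tibble(txt = c("NM_001234 | tp53 | chr17", "no id here",
                              "see ENSDARG00000000007 and GO:0001234"))
  expect_identical(extract_ids(t, "txt", "genbank")$txt_id,
                   c("NM_001234", NA, NA))
  expect_identical(extract_ids(t, "txt", "go_term")$txt_id,
                   c(NA, NA, "GO:0001234"))
  expect_identical(extract_ids(t, "txt", "ensembl_gene")$txt_id,
                   c(NA, NA, "ENSDARG00000000007"))
  expect_error(extract_ids(t, "txt", "("), "invalid regular expression")
  # 100 random composite cells vs an independent regexpr scan
  withr::local_seed(21)
  mk_cell <- function() {
    bits <- c(sprintf("NM_%06d", sample(1e5, 1)),
              sprintf("GO:%07d", sample(1e6, 1)),
              paste(sample(letters, 5), collapse = ""))
    paste(sample(bits, sample(1:3, 1)), collapse = " ; ")
  }
  cells <- vapply(1:100, function(i) mk_cell(), "")
  tt <- tibble::tibble(x = cells)
  for (preset in c("genbank", "go_term")) {
    rx <- id_patterns()[[preset]]
    oracle <- vapply(cells, function(cell) {
      m <- regexpr(rx, cell)
      if (m[1] == -1) NA_character_ else regmatches(cell, m)
    }, "", USE.NAMES = FALSE)
    expect_identical(extract_ids(tt, "x", preset)$x_id, oracle, info = preset)
  }
})
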