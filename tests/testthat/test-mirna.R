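test_that("consensus prediction equals the brute-force oracle at every setting", {
  d <- make_tiny_snapshot(seed = 31)
  s <- load_snapshot(d)
  mirnas <- sprintf("hsa-miR-%d", 1:10)
  for (k in 1:3) {
    for (lvl in c("pair", "gene")) {
      got <- suppressWarnings(
        predict_targets(mirnas, "hsa", min_agreement = k, level = lvl, snapshot = s))
      expect_identical(consensus_keys(got, lvl),
                       oracle_consensus(d, mirnas, "hsa", target_sources(), k, lvl),
                       info = sprintf("k=%d level=%s", k, lvl))
    }
  }
})

test_that("agreement flags sum to agreement_count and output is sorted", {
  d <- make_tiny_snapshot(seed = 13)
  s <- load_snapshot(d)
  got <- suppressWarnings(predict_targets(sprintf("hsa-miR-%d", 1:10), "hsa",
                                          min_agreement = 1, level = "pair", snapshot = s))
  expect_identical(got$agreement_count,
                   as.integer(got$in_targetscan + got$in_microcosm + got$in_mirnaorg))
  expect_true(all(diff(got$agreement_count) <= 0))
})

test_that("consensus output is monotone in min_agreement", {
  d <- make_tiny_snapshot(seed = 17)
  s <- load_snapshot(d)
  mirnas <- sprintf("hsa-miR-%d", 1:10)
  prev <- NULL
  for (k in 1:3) {
    keys <- consensus_keys(
      suppressWarnings(predict_targets(mirnas, "hsa", min_agreement = k,
                                       level = "gene", snapshot = s)), "gene")
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("predict_targets validates inputs and handles empties", {
  d <- make_tiny_snapshot()
  s <- load_snapshot(d)
  expect_identical(nrow(predict_targets(character(0), "hsa", snapshot = s)), 0L)
  expect_error(predict_targets("hsa-miR-1", "hsa", sources = c("targetscan", "microcosm"),
                               min_agreement = 3, snapshot = s), "min_agreement")
  expect_warning(predict_targets(c("hsa-miR-1", "hsa-miR-999"), "hsa",
                                 min_agreement = 1, snapshot = s),
                 "hsa-miR-999.*absent")
  # zebrafish predictions exist only in microcosm
  dre <- suppressWarnings(predict_targets(sprintf("dre-miR-%d", 1:10), "dre",
                                          sources = "microcosm", min_agreement = 1,
                                          snapshot = s))
  expect_true(all(dre$in_microcosm))
  expect_false(any(dre$in_targetscan))
})

test_that("regulatory_mirnas finds planted regulators by symbol and via entrez", {
  d <- make_tiny_snapshot(seed = 41)
  s <- load_snapshot(d)
  led <- read_fixture_ledger(d)
  conserved <- led[led$fact == "conserved_pair", ]
  g <- conserved$k2[1]          # an HSA symbol targeted in all three sources
  out <- regulatory_mirnas(g, species = "hsa", snapshot = s)
  expect_setequal(unique(out$source[out$gene == g]), target_sources())
  expect_true(conserved$k1[1] %in% out$mirna_id)
  # entrez input resolves through xref and gives the same result
  idx <- as.integer(sub("G", "", sub("^G0*", "", g)))
  ent <- sprintf("%d", 200000L + idx)
  out2 <- regulatory_mirnas(ent, id_type = "entrez", species = "hsa", snapshot = s)
  expect_setequal(paste(out2$mirna_id, out2$source),
                  paste(out$mirna_id, out$source))
  # a gene absent everywhere appears once with NA
  none <- regulatory_mirnas("gX", species = "hsa", snapshot = s)
  expect_identical(none$mirna_id, NA_character_)
})

test_that("metadata retrieval returns planted records, dedupes and normalizes", {
  d <- make_tiny_snapshot()
  s <- load_snapshot(d)
  raw <- readr::read_tsv(file.path(d, "mirna_metadata.tsv"), show_col_types = FALSE)
  rec <- raw[raw$species == "dre", ][1, ]
  out <- get_metadata(c(rec$mirna_id, rec$mirna_id, "dre-miR-999"), "dre", s)
  expect_identical(nrow(out), 2L)
  expect_identical(out$mature_accession[1], rec$mature_accession)
  expect_identical(out$mature_sequence[1], rec$mature_sequence)
  expect_false(out$matched[2])
  expect_identical(out$mature_accession[2], NA_character_)
})

test_that("mismatch counting matches spec'd hand cases", {
  base <- strrep("ACGU", 5)           # 20-mer
  s22 <- paste0(base, "AC")           # 22-mer
  flip <- function(seq, pos) {
    ch <- strsplit(seq, "")[[1]]
    ch[pos] <- setdiff(c("A", "C", "G", "U"), ch[pos])[1]
    paste(ch, collapse = "")
  }
  # identical sequences
  r <- homology_filter(tibble::tibble(seq_a = s22, seq_b = s22))
  expect_identical(r$n_mismatch, 0L)
  expect_true(r$seed_identical && r$pass)
  # single mismatch outside the seed still passes
  r <- homology_filter(tibble::tibble(seq_a = s22, seq_b = flip(s22, 10)))
  expect_identical(r$n_mismatch, 1L)
  expect_true(r$seed_identical && r$pass)
  # a seed-position mismatch fails despite being within the budget
  r <- homology_filter(tibble::tibble(seq_a = s22, seq_b = flip(s22, 3)))
  expect_identical(r$n_mismatch, 1L)
  expect_false(r$seed_identical)
  expect_false(r$pass)
  # a truncated 3' end counts as one mismatch
  r <- homology_filter(tibble::tibble(seq_a = s22, seq_b = substr(s22, 1, 21)))
  expect_identical(r$n_mismatch, 1L)
  expect_true(r$pass)
})

test_that("homology filter equals the position-scan oracle on random pairs", {
  withr::local_seed(97)
  pairs <- purrr::map(1:300, function(i) {
    a <- random_rna(sample(18:26, 1))
    b <- if (runif(1) < 0.4) {
      # correlated pair: copy with a few random edits
      ch <- strsplit(a, "")[[1]]
      for (p in sample(length(ch), sample(0:3, 1))) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1)
      }
      paste(ch, collapse = "")
    } else random_rna(sample(18:26, 1))
    tibble::tibble(seq_a = a, seq_b = b)
  }) |> dplyr::bind_rows()
  got <- homology_filter(pairs, max_mismatch = 1)
  for (i in seq_len(nrow(pairs))) {
    o <- oracle_mismatch(pairs$seq_a[i], pairs$seq_b[i])
    expect_identical(got$n_mismatch[i], o$n_mismatch)
    expect_identical(got$seed_identical[i], o$seed_identical)
    expect_identical(got$pass[i], o$n_mismatch <= 1 && o$seed_identical)
  }
  # max_mismatch = 0 passes exactly the identical sequences
  strict <- homology_filter(pairs, max_mismatch = 0)
  expect_identical(strict$pass, pairs$seq_a == pairs$seq_b)
})

test_that("homology filter normalizes DNA input and rejects bad alphabets", {
  r <- homology_filter(tibble::tibble(seq_a = tolower(gsub("U", "T", strrep("ACGU", 5))),
                                      seq_b = strrep("ACGU", 5)))
  expect_warning(
    homology_filter(tibble::tibble(seq_a = strrep("ACGU", 4), seq_b = strrep("ACGU", 4))),
    "18-26")
  expect_identical(r$n_mismatch, 0L)
  expect_error(homology_filter(tibble::tibble(id_a = "x1", seq_a = strrep("ACGX", 5),
                                              id_b = "y", seq_b = strrep("ACGU", 5))),
               "x1")
})
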