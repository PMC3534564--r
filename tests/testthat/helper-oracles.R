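# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths: set operations on
# the raw TSV files, position-by-position character scans, combinatorial
# enumeration, and a recompute-everything clustering loop.

# Small fixture spec used across tests (fast to generate, still exercises
# every planted structure).
tiny_spec <- function(seed = 11, ...) {
  args <- list(seed = seed, n_genes = 60, n_mirnas = 10, n_conserved_pairs = 8,
               n_two_source_pairs = 6, n_sig_mirnas = 10, n_sig_genes = 20,
               background_rate = 0.02,
               mismatch_profile = c(identical = 6, mismatch_out_seed = 2,
                                    mismatch_in_seed = 1, multi_mismatch = 1))
  args[names(list(...))] <- list(...)
  do.call(fixture_spec, args)
}

make_tiny_snapshot <- function(seed = 11, ...) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  generate_snapshot(tiny_spec(seed, ...), dir)
  dir
}

# Read one raw targets table straight from disk (bypasses load_snapshot).
raw_targets <- function(dir, source) {
  readr::read_tsv(file.path(dir, paste0("targets_", source, ".tsv")),
                  col_types = readr::cols(.default = readr::col_character()),
                  na = "NA", progress = FALSE)
}

# Brute-force consensus over the raw tables: per-source (miRNA, gene) pair
# sets / gene sets, membership counted with %in%.
oracle_consensus <- function(dir, mirnas, species, sources, min_agreement, level) {
  per_source <- lapply(sources, function(s) {
    tbl <- raw_targets(dir, s)
    tbl <- tbl[tbl$species == species & tbl$mirna_id %in% mirnas, ]
    if (level == "pair") {
      unique(paste(tbl$mirna_id, tbl$gene_symbol, sep = "\r"))
    } else {
      unique(tbl$gene_symbol)
    }
  })
  keys <- unique(unlist(per_source))
  counts <- vapply(keys, function(k) {
    sum(vapply(per_source, function(ks) k %in% ks, logical(1)))
  }, integer(1))
  sort(keys[counts >= min_agreement])
}

consensus_keys <- function(ct, level) {
  tbl <- tibble::as_tibble(ct)
  if (level == "pair") {
    sort(paste(tbl$mirna_id, tbl$gene_symbol, sep = "\r"))
  } else {
    sort(tbl$gene_symbol)
  }
}

# Position-by-position mismatch scan (independent of compare_mature_pair).
oracle_mismatch <- function(a, b) {
  ca <- utf8ToInt(a); cb <- utf8ToInt(b)
  ov <- min(length(ca), length(cb))
  mm <- 0L
  for (i in seq_len(ov)) if (ca[i] != cb[i]) mm <- mm + 1L
  mm <- mm + abs(length(ca) - length(cb))
  seed_ok <- TRUE
  if (ov < 8) seed_ok <- FALSE else {
    for (i in 2:8) if (ca[i] != cb[i]) seed_ok <- FALSE
  }
  list(n_mismatch = mm, seed_identical = seed_ok)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Exact hypergeometric upper tail by direct combinatorial summation.
oracle_hyper_upper <- function(N, K, n, k) {
  js <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Naive O(n^3) agglomerative centroid clustering: at every step, recompute
# every cluster centroid from the raw member rows, scan all pairs, merge the
# closest (lexicographically smallest node-id pair on ties).
oracle_upgmc <- function(x) {
  n <- nrow(x)
  members <- lapply(seq_len(n), identity)   # node id -> row indices
  active <- seq_len(n)
  merges <- list()
  for (step in seq_len(n - 1)) {
    best <- NULL; best_d <- Inf
    for (ii in seq_len(length(active) - 1)) {
      for (jj in (ii + 1):length(active)) {
        a <- active[ii]; b <- active[jj]
        ca <- colMeans(x[members[[a]], , drop = FALSE])
        cb <- colMeans(x[members[[b]], , drop = FALSE])
        d <- sqrt(sum((ca - cb)^2))
        pair <- sort(c(a, b))
        if (d < best_d - 1e-12 ||
            (abs(d - best_d) <= 1e-12 &&
               (is.null(best) || pair[1] < best[1] ||
                  (pair[1] == best[1] && pair[2] < best[2])))) {
          best_d <- d; best <- pair
        }
      }
    }
    new_node <- n + step
    members[[new_node]] <- c(members[[best[1]]], members[[best[2]]])
    merges[[step]] <- data.frame(node_a = best[1], node_b = best[2],
                                 height = best_d, new_node = new_node)
    active <- c(setdiff(active, best), new_node)
  }
  do.call(rbind, merges)
}
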