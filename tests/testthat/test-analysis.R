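test_that("the fully-overlapping draw gives the exact enumeration value 1/252", {
  gsc <- gene_set_collection(list(s1 = letters[1:5]), universe = letters[1:10])
  res <- enrich(letters[1:5], gsc)
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-14)
  # single tested set: q equals p
  expect_identical(res$q_value, res$p_value)
})

test_that("zero overlap gives p = 1", {
  gsc <- gene_set_collection(list(s1 = letters[1:4]), universe = letters[1:12])
  res <- enrich(letters[5:8], gsc)
  expect_equal(res$p_value, 1, tolerance = 1e-14)
})

test_that("p-values match combinatorial enumeration on random small instances", {
  withr::local_seed(2)
  for (i in 1:40) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    universe <- sprintf("u%02d", 1:N)
    set <- sample(universe, K)
    query <- sample(universe, n)
    gsc <- gene_set_collection(list(s = set), universe = universe)
    res <- enrich(query, gsc)
    k <- length(intersect(set, query))
    expect_identical(res$k, k)
    expect_equal(res$p_value, oracle_hyper_upper(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("BH q-values dominate p-values and are rank-monotone", {
  withr::local_seed(3)
  universe <- sprintf("u%03d", 1:60)
  sets <- purrr::map(1:12, function(i) sample(universe, sample(5:20, 1)))
  names(sets) <- sprintf("s%02d", 1:12)
  gsc <- gene_set_collection(sets, universe = universe)
  res <- enrich(sample(universe, 15), gsc)
  expect_true(all(res$q_value >= res$p_value))
  expect_true(all(diff(res$q_value) >= -1e-15))  # sorted by p: monotone ranks
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"), tolerance = 1e-15)
})

test_that("enrichment is invariant to query and set order and logs dropped genes", {
  withr::local_seed(4)
  universe <- sprintf("u%03d", 1:40)
  sets <- list(a = universe[1:10], b = universe[5:25], c = universe[30:40])
  query <- c(sample(universe[1:20], 10), "not_in_universe")
  g1 <- gene_set_collection(sets, universe)
  g2 <- gene_set_collection(sets[c(3, 1, 2)], universe)
  expect_message(r1 <- enrich(query, g1), "dropped 1")
  r2 <- suppressMessages(enrich(rev(query), g2))
  expect_equal(r1[order(r1$term_id), ], r2[order(r2$term_id), ],
               ignore_attr = TRUE)
})

test_that("empty universes and empty queries are handled per contract", {
  expect_error(gene_set_collection(list(a = "x"), character(0)), "non-empty")
  expect_warning(gsc <- gene_set_collection(list(a = "zz", b = c("u1", "u2")),
                                            universe = c("u1", "u2", "u3")),
                 "dropped 1 empty")
  expect_warning(res <- enrich("not_here", gsc), "empty")
  expect_identical(nrow(res), 0L)
})

test_that("two points merge at their distance; identical rows merge at zero", {
  x <- rbind(c(0, 0), c(3, 4))
  hc <- hcluster(x)
  expect_identical(nrow(hc$merges), 1L)
  expect_equal(hc$merges$height, 5)
  x3 <- rbind(c(1, 1), c(1, 1), c(1, 1))
  hc3 <- hcluster(x3)
  expect_equal(hc3$merges$height, c(0, 0))
  # deterministic lexicographic tie-break
  expect_identical(hc3$merges$node_a[1], 1L)
  expect_identical(hc3$merges$node_b[1], 2L)
})

test_that("merge sequences equal the naive recompute-all-centroids oracle", {
  withr::local_seed(12)
  for (i in 1:25) {
    x <- matrix(rnorm(sample(4:10, 1) * 4), ncol = 4)
    hc <- hcluster(x)
    o <- oracle_upgmc(x)
    expect_identical(hc$merges$node_a, o$node_a, info = paste("case", i))
    expect_identical(hc$merges$node_b, o$node_b, info = paste("case", i))
    expect_equal(hc$merges$height, o$height, tolerance = 1e-9)
  }
})

test_that("scaling the matrix scales heights and preserves the merge sequence", {
  withr::local_seed(14)
  x <- matrix(rnorm(8 * 3), ncol = 3)
  a <- hcluster(x)
  b <- hcluster(2.5 * x)
  expect_identical(a$merges$node_a, b$merges$node_a)
  expect_identical(a$merges$node_b, b$merges$node_b)
  expect_equal(b$merges$height, 2.5 * a$merges$height, tolerance = 1e-9)
})

test_that("degenerate clustering inputs are fatal with informative messages", {
  expect_error(hcluster(matrix(1, nrow = 1)), "at least two")
  xm <- matrix(rnorm(6), nrow = 3, dimnames = list(c("a", "b", "c"), NULL))
  xm[2, 1] <- NA
  expect_error(hcluster(xm), "missing value in row `b`")
  expect_error(hcluster(data.frame(x = c("p", "q"))), "numeric")
})

test_that("dendrograms convert to hclust and export parseable Newick", {
  withr::local_seed(15)
  x <- matrix(rnorm(6 * 3), ncol = 3,
              dimnames = list(sprintf("g%d", 1:6), NULL))
  hc <- hcluster(x)
  h <- as.hclust(hc)
  expect_s3_class(h, "hclust")
  expect_identical(sort(h$order), 1:6)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, path)
  phy <- ape::read.tree(path)
  expect_identical(sort(phy$tip.label), sort(rownames(x)))
})

test_that("a planted over-represented set attains the minimum p-value", {
  withr::local_seed(16)
  universe <- sprintf("u%03d", 1:100)
  planted <- universe[1:20]
  decoys <- purrr::map(1:8, function(i) sample(universe, 20))
  sets <- c(list(planted = planted), setNames(decoys, sprintf("d%d", 1:8)))
  gsc <- gene_set_collection(sets, universe)
  query <- c(planted[1:15], sample(universe[60:100], 5))
  res <- enrich(query, gsc)
  expect_identical(res$term_id[1], "planted")
})
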