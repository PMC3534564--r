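# Downstream analyses: hypergeometric gene-set enrichment against a declared
# background universe, and agglomerative hierarchical clustering with exact
# centroid (UPGMC) linkage.

#' Build a gene-set collection against a declared background
#'
#' Intersects each set with the universe; empty sets are dropped with a
#' warning. Gene symbols are compared case-insensitively but stored as given
#' in the universe.
#'
#' @param sets A long tibble with columns `term_id`, `term_name`,
#'   `gene_symbol` (e.g. from [read_gmt()] or a long
#'   [annotate_genes()] result), or a named list of character vectors.
#' @param universe Character vector of background gene symbols (the declared
#'   background, e.g. all genes on the array platform).
#' @param term_names Optional named character vector of descriptions when
#'   `sets` is a list.
#' @return A `gene_set_collection`: list with `universe`, `sets` (named list
#'   of member vectors) and `term_names`.
#' @export
gene_set_collection <- function(sets, universe, term_names = NULL) {
  if (length(universe) == 0) abort("`universe` must be non-empty")
  universe <- unique(as.character(universe))
  uni_key <- tolower(universe)

  if (is.data.frame(sets)) {
    sets <- as_tibble(sets)
    stopifnot(all(c("term_id", "gene_symbol") %in% names(sets)))
    if (!"term_name" %in% names(sets)) sets$term_name <- sets$term_id
    term_names <- sets |> distinct(.data$term_id, .data$term_name)
    term_names <- setNames(term_names$term_name, term_names$term_id)
    members <- split(as.character(sets$gene_symbol), sets$term_id)
  } else {
    members <- sets
    if (is.null(names(members))) abort("`sets` list must be named by term id")
    if (is.null(term_names)) term_names <- setNames(names(members), names(members))
  }

  clipped <- map(members, function(g) {
    universe[uni_key %in% unique(tolower(g))]
  })
  empty <- names(clipped)[lengths(clipped) == 0]
  if (length(empty) > 0) {
    warn(sprintf("dropped %d empty set(s) after intersecting with the universe",
                 length(empty)))
    clipped <- clipped[lengths(clipped) > 0]
  }
  structure(list(universe = universe, sets = clipped,
                 term_names = as.list(term_names)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Hypergeometric gene-set enrichment
#'
#' For each set, tests over-representation of the query in the set with the
#' exact hypergeometric upper tail P(X >= k), where the universe of size N
#' is the declared background, K is the set size, n the query size after
#' intersection with the universe, and k the overlap. P-values are adjusted
#' across all tested sets with Benjamini-Hochberg. Query genes outside the
#' universe are dropped with a logged count.
#'
#' @param query Character vector of gene symbols.
#' @param gsc A [gene_set_collection()].
#' @param alpha Significance level (default 0.05). `significant` flags raw
#'   p <= alpha; `significant_fdr` flags q <= alpha (recommended).
#' @return A tibble of class `enrichment_result`, sorted by p-value, with
#'   columns `term_id`, `term_name`, `N`, `K`, `n`, `k`, `p_value`,
#'   `q_value`, `significant`, `significant_fdr`.
#' @export
#' @examples
#' gsc <- gene_set_collection(list(s1 = letters[1:5]), universe = letters[1:10])
#' enrich(letters[1:5], gsc)
enrich <- function(query, gsc, alpha = 0.05) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  if (length(gsc$universe) == 0) abort("empty universe")
  uni_key <- tolower(gsc$universe)
  qk <- unique(tolower(as.character(query)))
  in_uni <- qk %in% uni_key
  n_dropped <- sum(!in_uni)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d query gene(s) outside the universe", n_dropped))
  }
  qk <- qk[in_uni]
  cols <- tibble(term_id = character(0), term_name = character(0),
                 N = integer(0), K = integer(0), n = integer(0), k = integer(0),
                 p_value = numeric(0), q_value = numeric(0),
                 significant = logical(0), significant_fdr = logical(0))
  if (length(qk) == 0) {
    warn("query is empty after intersection with the universe")
    return(structure(cols, class = c("enrichment_result", class(cols)),
                     alpha = alpha, n_query = 0L, n_dropped = n_dropped))
  }
  N <- length(gsc$universe)
  n <- length(qk)
  res <- imap(gsc$sets, function(members, id) {
    K <- length(members)
    k <- sum(tolower(members) %in% qk)
    # upper tail P(X >= k)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term_id = id,
           term_name = as.character(gsc$term_names[[id]] %||% id),
           N = N, K = K, n = n, k = as.integer(k), p_value = p)
  })
  out <- bind_rows(res) |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH"),
           significant = .data$p_value <= alpha,
           significant_fdr = .data$q_value <= alpha) |>
    arrange(.data$p_value, .data$term_id)
  structure(out, class = c("enrichment_result", class(out)),
            alpha = alpha, n_query = n, n_dropped = n_dropped)
}

#' Agglomerative hierarchical clustering with exact centroid linkage
#'
#' Euclidean-distance agglomerative clustering. At each step the pair of
#' clusters with the smallest inter-centroid Euclidean distance is merged;
#' the new cluster's centroid is the size-weighted mean of the merged
#' centroids (exact UPGMC, no Lance-Williams update). Ties are broken by the
#' lexicographically smallest pair of node ids. Centroid linkage can produce
#' inversions (a merge lower than an earlier one); these are permitted and
#' flagged.
#'
#' Leaves are numbered 1..n in input row order; internal nodes continue from
#' n+1 in merge order. The leaf order is the recursive left-first traversal
#' of the final tree.
#'
#' @param x A numeric matrix or data frame of numeric columns; rows are the
#'   objects to cluster. At least two rows; missing values are fatal.
#' @param distance Distance metric; only `"euclidean"`.
#' @param linkage Linkage; only `"centroid"`.
#' @return A `centroid_dendrogram`: list with `merges` (tibble: `step`,
#'   `node_a`, `node_b`, `height`, `new_node`, `inversion`), `labels`,
#'   `order` (leaf indices in display order) and `n`.
#' @seealso [write_newick()], [as.hclust.centroid_dendrogram()]
#' @export
hcluster <- function(x, distance = "euclidean", linkage = "centroid") {
  if (!identical(distance, "euclidean")) abort("only euclidean distance is supported")
  if (!identical(linkage, "centroid")) abort("only centroid linkage is supported")
  labels <- rownames(x) %||% paste0("r", seq_len(nrow(x)))
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("all clustered columns must be numeric")
  if (nrow(x) < 2) abort("clustering needs at least two rows")
  if (anyNA(x)) {
    bad <- which(apply(x, 1, anyNA))[1]
    abort(sprintf("missing value in row `%s`", labels[bad]))
  }
  n <- nrow(x)

  centroids <- lapply(seq_len(n), function(i) x[i, ])
  sizes <- rep(1L, n)
  active <- seq_len(n)
  merges <- vector("list", n - 1L)
  children <- list()
  last_height <- -Inf

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL
    best_d <- Inf
    for (ii in seq_len(k - 1L)) {
      for (jj in (ii + 1L):k) {
        a <- active[ii]; b <- active[jj]
        d <- sqrt(sum((centroids[[a]] - centroids[[b]])^2))
        pair <- sort(c(a, b))
        if (d < best_d - 1e-12 ||
            (abs(d - best_d) <= 1e-12 &&
               (is.null(best) || pair[1] < best[1] ||
                  (pair[1] == best[1] && pair[2] < best[2])))) {
          best_d <- d
          best <- pair
        }
      }
    }
    new_node <- n + step
    wa <- sizes[best[1]]; wb <- sizes[best[2]]
    centroids[[new_node]] <- (wa * centroids[[best[1]]] + wb * centroids[[best[2]]]) /
      (wa + wb)
    sizes[new_node] <- wa + wb
    children[[as.character(new_node)]] <- best
    merges[[step]] <- tibble(step = step, node_a = best[1], node_b = best[2],
                             height = best_d, new_node = new_node,
                             inversion = best_d < last_height - 1e-12)
    last_height <- best_d
    active <- c(setdiff(active, best), new_node)
  }
  merges <- bind_rows(merges)

  # Left-first recursive traversal for the displayed leaf order.
  leaf_order <- integer(0)
  visit <- function(node) {
    if (node <= n) {
      leaf_order[length(leaf_order) + 1L] <<- node
    } else {
      ch <- children[[as.character(node)]]
      visit(ch[1]); visit(ch[2])
    }
  }
  visit(n + (n - 1L))

  structure(list(merges = merges, labels = labels, order = leaf_order, n = n),
            class = "centroid_dendrogram")
}

#' @export
print.centroid_dendrogram <- function(x, ...) {
  cat(sprintf("<centroid_dendrogram> %d leaves, %d merges, %d inversion(s)\n",
              x$n, nrow(x$merges), sum(x$merges$inversion)))
  invisible(x)
}

#' Convert a centroid dendrogram to an hclust object
#'
#' @param x A `centroid_dendrogram`.
#' @param ... Unused.
#' @return A `stats::hclust` object (heights may be non-monotone when the
#'   tree contains inversions).
#' @export
as.hclust.centroid_dendrogram <- function(x, ...) {
  n <- x$n
  recode <- function(node) {
    ifelse(node <= n, -node, node - n)
  }
  merge <- cbind(recode(x$merges$node_a), recode(x$merges$node_b))
  structure(list(merge = merge, height = x$merges$height, order = x$order,
                 labels = x$labels, method = "centroid",
                 dist.method = "euclidean",
                 call = match.call()),
            class = "hclust")
}

#' Write a dendrogram as Newick
#'
#' Branch lengths are differences between merge heights, which can be
#' negative across inversions.
#'
#' @param dendro A `centroid_dendrogram` or `hclust`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(dendro, path) {
  hc <- if (inherits(dendro, "centroid_dendrogram")) as.hclust(dendro) else dendro
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}
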