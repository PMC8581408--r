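#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a query list drawn from a
#' stated universe. With `N` universe genes, `K` of which belong to the set
#' (after intersecting the set with the universe), and a query of size `n`
#' overlapping the set in `k` genes, the upper-tail hypergeometric
#' probability `P(X >= k)` is the chance of at least as large an overlap
#' under uniform sampling without replacement. P values are BH-adjusted
#' across the tested sets. Sets whose universe-intersected size falls
#' outside `[min_size, max_size]` are skipped.
#'
#' The conventional universe is the set of genes actually tested by the
#' corresponding model (after the zero-count filter), not the whole genome.
#'
#' @param query character vector of gene ids; must be a subset of
#'   `universe`.
#' @param universe character vector of background gene ids.
#' @param collection a [gene_set_collection()].
#' @param min_size,max_size set-size bounds after universe intersection
#'   (defaults 10 and 500).
#' @param alpha enrichment threshold on adjusted p (default 0.01).
#' @return an `ora_table` data.frame sorted by p: `set`, `k` (overlap),
#'   `K` (set size in universe), `n` (query size), `N` (universe size),
#'   `pvalue`, `padj`, `enriched` (`padj < alpha`), `genes` (comma-joined
#'   overlap). Empty query returns an empty table with a warning.
#' @export
ora <- function(query, universe, collection, min_size = 10L, max_size = 500L,
                alpha = 0.01) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(query)
  universe <- unique(universe)
  if (!all(query %in% universe)) {
    stop_fustx("query contains genes outside the universe")
  }
  empty <- data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), pvalue = numeric(),
                      padj = numeric(), enriched = logical(),
                      genes = character(), stringsAsFactors = FALSE)
  class(empty) <- c("ora_table", "data.frame")
  if (length(query) == 0L) {
    warning("empty query; returning empty table")
    return(empty)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    K <- length(members)
    if (K < min_size || K > max_size) return(NULL)
    hit <- intersect(query, members)
    k <- length(hit)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, pvalue = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  tab <- do.call(rbind, rows)
  tab$padj <- bh_adjust(tab$pvalue)
  tab$enriched <- tab$padj < alpha
  tab <- tab[order(tab$padj, tab$pvalue, tab$set),
             c("set", "k", "K", "n", "N", "pvalue", "padj", "enriched",
               "genes")]
  rownames(tab) <- NULL
  class(tab) <- c("ora_table", "data.frame")
  tab
}

#' Prune redundant gene sets by member overlap
#'
#' Walks the table in order of increasing adjusted p (ties broken by set
#' name) and keeps a set only if its Jaccard similarity with every
#' already-kept set stays below `jaccard_threshold`. This is an
#' overlap-based stand-in for the common display-time practice of removing
#' near-duplicate pathways before plotting top enrichments.
#'
#' @param table an `ora_table` from [ora()].
#' @param collection the [gene_set_collection()] the table was computed
#'   from.
#' @param jaccard_threshold similarity at or above which the later set is
#'   pruned (default 0.7); `1` prunes only exactly identical sets.
#' @param universe optional universe to intersect members with before
#'   comparing (the same used in [ora()]).
#' @return the pruned `ora_table`, original ordering retained.
#' @export
prune_redundant <- function(table, collection, jaccard_threshold = 0.7,
                            universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  check_number(jaccard_threshold, "jaccard_threshold", lower = 0, upper = 1)
  if (nrow(table) == 0L) return(table)
  ord <- order(table$padj, table$set)
  tab <- table[ord, , drop = FALSE]
  members <- lapply(tab$set, function(nm) {
    m <- collection$sets[[nm]]
    if (!is.null(universe)) m <- intersect(m, universe)
    unique(m)
  })
  keep <- logical(nrow(tab))
  kept <- list()
  for (i in seq_len(nrow(tab))) {
    jac <- vapply(kept, function(km) {
      length(intersect(km, members[[i]])) / length(union(km, members[[i]]))
    }, numeric(1))
    redundant <- if (jaccard_threshold == 1) {
      any(jac == 1)
    } else {
      any(jac >= jaccard_threshold)
    }
    if (!redundant) {
      keep[i] <- TRUE
      kept <- c(kept, members[i])
    }
  }
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  out
}

#' Bipartite gene-concept network of top enrichments
#'
#' Edge list linking each of the `top_k` retained sets to its overlapping
#' query genes, with each gene annotated by the subset of pools in which it
#' is significant — the tabular backbone of a gene-concept plot where each
#' gene is drawn as a pie over pool memberships.
#'
#' @param table an `ora_table` (typically after [prune_redundant()]).
#' @param pools named list of `gene_pool`s used for the membership
#'   annotation.
#' @param top_k number of top sets to include (default 5).
#' @return data.frame with columns `set`, `gene`, `pools` (comma-joined
#'   pool labels containing the gene) and `n_pools`.
#' @export
concept_network <- function(table, pools, top_k = 5L) {
  top_k <- check_count(top_k, "top_k", lower = 1L)
  use <- head(seq_len(nrow(table)), top_k)
  pool_members <- lapply(pools, `[[`, "gene")
  rows <- lapply(use, function(i) {
    genes <- strsplit(table$genes[i], ",", fixed = TRUE)[[1]]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) return(NULL)
    ann <- vapply(genes, function(g) {
      paste(names(pool_members)[vapply(pool_members, function(m) g %in% m,
                                       logical(1))], collapse = ",")
    }, character(1))
    data.frame(set = table$set[i], gene = genes, pools = unname(ann),
               n_pools = ifelse(ann == "", 0L,
                                lengths(strsplit(ann, ",", fixed = TRUE))),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(set = character(), gene = character(),
                      pools = character(), n_pools = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
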