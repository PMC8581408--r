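#' Merge linear and exponential significant genes into one pool
#'
#' For one (metric, timepoint) pair, the pool is the union of the genes
#' significant (adjusted p below `alpha`) under the linear and exponential
#' model forms. Each member's correlation sign and best adjusted p are
#' taken from the contributing model with the smaller adjusted p; genes
#' significant in both forms with opposite coefficient signs are resolved
#' the same way and recorded in the `conflicts` attribute for audit.
#'
#' @param fit_linear,fit_exp `fit_table`s over the same gene universe.
#' @param alpha significance threshold on adjusted p (default 0.05).
#' @param label pool label, e.g. `"CE_6h"`.
#' @return a `gene_pool`: data.frame with columns `gene`, `sign` (`"+"` or
#'   `"-"`), `best_padj`, plus attributes `label`, `universe`, `conflicts`.
#' @export
merge_pool <- function(fit_linear, fit_exp, alpha = 0.05, label = "pool") {
  if (!setequal(fit_linear$gene, fit_exp$gene)) {
    stop_fustx("fit tables cover different gene universes")
  }
  fe <- fit_exp[match(fit_linear$gene, fit_exp$gene), ]
  sig_lin <- !is.na(fit_linear$padj) & fit_linear$padj < alpha
  sig_exp <- !is.na(fe$padj) & fe$padj < alpha
  member <- sig_lin | sig_exp
  # smaller adjusted p decides which model contributes sign and best p;
  # a model that is not significant never decides
  p_lin <- ifelse(sig_lin, fit_linear$padj, Inf)
  p_exp <- ifelse(sig_exp, fe$padj, Inf)
  from_lin <- p_lin <= p_exp
  sign_num <- ifelse(from_lin, sign(fit_linear$coef), sign(fe$coef))
  best <- pmin(p_lin, p_exp)
  conflicts <- fit_linear$gene[sig_lin & sig_exp &
                                 sign(fit_linear$coef) != sign(fe$coef)]
  if (length(conflicts)) {
    message(label, ": ", length(conflicts),
            " gene(s) significant in both forms with opposite signs; ",
            "sign taken from the smaller adjusted p")
  }
  pool <- data.frame(gene = fit_linear$gene[member],
                     sign = ifelse(sign_num[member] >= 0, "+", "-"),
                     best_padj = best[member],
                     row.names = NULL, stringsAsFactors = FALSE)
  pool <- pool[order(pool$best_padj, pool$gene), ]
  rownames(pool) <- NULL
  attr(pool, "label") <- label
  attr(pool, "universe") <- fit_linear$gene
  attr(pool, "conflicts") <- conflicts
  class(pool) <- c("gene_pool", "data.frame")
  pool
}

#' Build the four metric-by-timepoint pools from fitted models
#'
#' Pairs each metric and timepoint's linear and exponential `fit_table`s
#' (named `<metric>_<form>_<timepoint>` as produced by [run_models()]) and
#' merges each pair with [merge_pool()]. Pairs with a missing member are
#' skipped with a message.
#'
#' @param fits named list of `fit_table`s from [run_models()].
#' @param alpha significance threshold.
#' @return named list of `gene_pool`s labeled `<metric>_<timepoint>`.
#' @export
make_pools <- function(fits, alpha = 0.05) {
  meta <- strsplit(names(fits), "_", fixed = TRUE)
  key <- vapply(meta, function(x) paste(x[1], x[3], sep = "_"), character(1))
  pools <- list()
  for (k in unique(key)) {
    parts <- strsplit(k, "_", fixed = TRUE)[[1]]
    lin <- fits[[paste(parts[1], "linear", parts[2], sep = "_")]]
    ex <- fits[[paste(parts[1], "exponential", parts[2], sep = "_")]]
    if (is.null(lin) || is.null(ex)) {
      message("pool ", k, " skipped: missing linear or exponential fit")
      next
    }
    pools[[k]] <- merge_pool(lin, ex, alpha = alpha, label = k)
  }
  pools
}

#' Overlap (Jaccard) fraction between two gene sets
#'
#' `|intersection| / |union|`; reported per linear/exponential model pair
#' as a similarity diagnostic. Two empty sets are defined to overlap fully
#' (1, with a warning).
#'
#' @param set1,set2 character vectors of gene ids.
#' @return a fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(set1, set2) {
  set1 <- unique(set1)
  set2 <- unique(set2)
  u <- union(set1, set2)
  if (length(u) == 0L) {
    warning("both sets empty; overlap defined as 1")
    return(1)
  }
  length(intersect(set1, set2)) / length(u)
}

#' Exclusive (UpSet) intersection accounting over pools
#'
#' Partitions the union of the pools' direction-filtered members into
#' exclusive subset bins: each gene is counted once, in the bin of exactly
#' the pools that contain it. Bins are ordered by size descending, then by
#' subset label, so output is deterministic.
#'
#' @param pools named list of `gene_pool`s (typically the 4 metric x
#'   timepoint pools).
#' @param direction `"+"`, `"-"`, or `"both"`: restrict to positively or
#'   negatively correlated members before binning.
#' @return data.frame with columns `subset` (pool labels joined by `&`),
#'   `degree` (number of pools in the subset), `exclusive_count`, and
#'   `genes` (comma-joined member list).
#' @export
upset_intersections <- function(pools, direction = c("+", "-", "both")) {
  direction <- match.arg(direction)
  labels <- names(pools)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop_fustx("pools must carry unique names")
  }
  members <- lapply(pools, function(p) {
    if (direction == "both") p$gene else p$gene[p$sign == direction]
  })
  all_genes <- sort(unique(unlist(members)))
  if (length(all_genes) == 0L) {
    return(data.frame(subset = character(), degree = integer(),
                      exclusive_count = integer(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  membership <- vapply(members, function(m) all_genes %in% m,
                       logical(length(all_genes)))
  if (is.null(dim(membership))) membership <- matrix(membership, nrow = 1L)
  subset_label <- apply(membership, 1L, function(row) {
    paste(labels[row], collapse = "&")
  })
  split_genes <- split(all_genes, subset_label)
  tab <- data.frame(
    subset = names(split_genes),
    degree = vapply(strsplit(names(split_genes), "&", fixed = TRUE),
                    length, integer(1)),
    exclusive_count = lengths(split_genes),
    genes = vapply(split_genes, paste, character(1), collapse = ","),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$exclusive_count, tab$subset), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
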