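#' Drop all-zero genes from a count matrix
#'
#' Genes with zero counts in every sample carry no information and break
#' geometric means; they are removed before normalization and modeling.
#'
#' @param counts genes x samples matrix of nonnegative integers.
#' @param quiet suppress the removal message.
#' @return the filtered matrix; the number removed is reported via `message`.
#' @export
drop_zero_genes <- function(counts, quiet = FALSE) {
  counts <- check_counts(counts)
  keep <- rowSums(counts) > 0
  if (!all(keep) && !quiet) {
    message(sum(!keep), " all-zero gene(s) dropped")
  }
  counts[keep, , drop = FALSE]
}

check_counts <- function(counts) {
  if (!is.matrix(counts)) stop_fustx("'counts' must be a matrix")
  if (any(counts < 0)) stop_fustx("counts must be nonnegative")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_fustx("'counts' must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop_fustx("gene and sample ids must be unique")
  }
  counts
}

#' Median-of-ratios size factors
#'
#' The per-sample scaling factor is the median, over genes with a positive
#' geometric mean across all samples, of the ratio of the sample's count to
#' that geometric mean — the standard median-of-ratios estimator for
#' sequencing-depth normalization of RNA-seq counts. Factors are reported
#' as computed, without rescaling.
#'
#' @param counts genes x samples nonnegative matrix.
#' @param method `"ratio"` (default) requires at least one gene with
#'   positive counts in every sample; `"poscounts"` falls back to a
#'   pseudo-reference using the geometric mean over positive counts only,
#'   for sparse matrices where no such gene exists.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts, method = c("ratio", "poscounts")) {
  counts <- check_counts(counts)
  method <- match.arg(method)
  if (method == "ratio") {
    log_geo <- rowMeans(log(counts))
    use <- is.finite(log_geo)
    if (!any(use)) {
      stop_fustx(paste0(
        "no gene has nonzero counts in all samples; ",
        "use method = \"poscounts\" for a pseudo-reference fallback"))
    }
  } else {
    lc <- log(counts)
    lc[!is.finite(lc)] <- NA
    log_geo <- rowMeans(lc, na.rm = TRUE) # geometric mean over positive counts
    use <- rowSums(counts > 0) > 0
  }
  sf <- apply(counts[use, , drop = FALSE], 2L, function(col) {
    r <- col / exp(log_geo[use])
    stats::median(r[is.finite(r) & r > 0])
  })
  if (any(!is.finite(sf) | sf <= 0)) {
    stop_fustx("size factor estimation produced non-positive factors")
  }
  sf
}

#' Shifted-log transform and PCA diagnostic
#'
#' Applies a variance-stabilizing-style transform `log2(count / sf + 1)` to
#' normalized counts, ranks genes by transformed variance, and computes
#' principal components of the centered top-gene matrix via SVD. Component
#' signs are fixed by making the largest-magnitude gene loading of each
#' component positive, so results are deterministic.
#'
#' @param counts genes x samples matrix.
#' @param sf size factors from [size_factors()].
#' @param n_top_genes number of most-variable genes used (default 500,
#'   capped at the number of genes).
#' @param n_components number of components (default 2).
#' @return list with `x` (samples x components coordinate matrix),
#'   `explained` (variance fraction per component), `sdev`, and
#'   `top_genes`.
#' @export
vst_pca <- function(counts, sf, n_top_genes = 500L, n_components = 2L) {
  counts <- check_counts(counts)
  stopifnot(length(sf) == ncol(counts), all(sf > 0))
  n_components <- check_count(n_components, "n_components", lower = 1L)
  if (n_components >= ncol(counts)) {
    stop_fustx("need more samples than components")
  }
  vst <- log2(sweep(counts, 2L, sf, "/") + 1)
  v <- apply(vst, 1L, stats::var)
  top <- head(order(v, decreasing = TRUE), min(n_top_genes, nrow(vst)))
  m <- t(vst[top, , drop = FALSE]) # samples x genes
  m <- sweep(m, 2L, colMeans(m))
  sv <- svd(m, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  x <- sweep(sv$u %*% diag(sv$d[seq_len(n_components)], n_components), 2L,
             flip, "*")
  dimnames(x) <- list(colnames(counts), paste0("PC", seq_len(n_components)))
  total_var <- sum(sv$d^2)
  list(x = x,
       explained = sv$d[seq_len(n_components)]^2 / total_var,
       sdev = sv$d / sqrt(nrow(m) - 1),
       top_genes = rownames(vst)[top])
}

#' CE-MBA collinearity diagnostic
#'
#' Ordinary least-squares regression of MBA on CE over FUS-treated samples
#' with both metrics measured, reporting the coefficient of determination
#' and the variance inflation factor `VIF = 1 / (1 - R^2)`. With two
#' predictors, a VIF well below the conventional thresholds (5-10) supports
#' entering CE and MBA as separate continuous covariates.
#'
#' @param samples data.frame with columns `fus`, `ce`, `mba` (NA allowed
#'   for unmeasured MBA).
#' @return list of class `collinearity_report`: `r_squared`, `vif`, `slope`,
#'   `intercept`, `n_samples_used`. A perfect fit reports `vif = Inf` with a
#'   warning.
#' @export
collinearity <- function(samples) {
  stopifnot(all(c("fus", "ce", "mba") %in% names(samples)))
  use <- samples$fus == 1 & !is.na(samples$ce) & !is.na(samples$mba)
  if (sum(use) < 3L) {
    stop_fustx("need at least 3 FUS-treated samples with paired CE and MBA")
  }
  ce <- samples$ce[use]
  mba <- samples$mba[use]
  if (stats::var(ce) == 0) stop_fustx("zero variance in CE")
  fit <- stats::lm(mba ~ ce)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((mba - mean(mba))^2)
  vif <- if (r2 >= 1 - .Machine$double.eps^0.5) {
    warning("perfect collinearity: VIF is infinite")
    Inf
  } else {
    1 / (1 - r2)
  }
  structure(list(r_squared = r2, vif = vif,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 n_samples_used = sum(use)),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat(sprintf("MBA ~ CE over %d samples: R^2 = %.3f, VIF = %.2f, slope = %.3g\n",
              x$n_samples_used, x$r_squared, x$vif, x$slope))
  invisible(x)
}
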