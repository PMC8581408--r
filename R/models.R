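#' One regression-model permutation
#'
#' A model is one permutation of dose form (`linear` or `exponential`),
#' BBBD metric (`CE` or `MBA`) and harvest timepoint (`6h` or `24h`). With
#' the canonical log link, the exponential form enters the raw metric as
#' the covariate (expression proportional to `exp(beta1 * metric)`), while
#' the linear form enters `ln(metric)` (expression proportional to
#' `metric^beta1`, containing the directly proportional case `beta1 = 1`);
#' the assigned value 1 for untreated samples then maps the linear-form
#' covariate exactly to 0.
#'
#' @param metric `"CE"` or `"MBA"`.
#' @param form `"linear"` or `"exponential"`.
#' @param timepoint `"6h"` or `"24h"` (any level present in the metadata).
#' @param covariates ordered subset of `c("sex", "anesthesia", "batch")`;
#'   each is included only when at least two levels are present among the
#'   model's samples.
#' @param alpha_threshold adjusted-p significance threshold (default 0.05).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(metric = c("CE", "MBA"),
                       form = c("linear", "exponential"),
                       timepoint = "6h",
                       covariates = c("sex", "anesthesia", "batch"),
                       alpha_threshold = 0.05) {
  metric <- match.arg(metric)
  form <- match.arg(form)
  stopifnot(is.character(timepoint), length(timepoint) == 1L)
  if (!all(covariates %in% c("sex", "anesthesia", "batch"))) {
    stop_fustx("covariates must be a subset of sex, anesthesia, batch")
  }
  check_number(alpha_threshold, "alpha_threshold", lower = 0, upper = 1)
  structure(list(metric = metric, form = form, timepoint = timepoint,
                 covariates = covariates, alpha_threshold = alpha_threshold,
                 name = paste(metric, form, timepoint, sep = "_")),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec %s: %s form of %s at %s, covariates [%s], alpha %g\n",
              x$name, x$form, x$metric, x$timepoint,
              paste(x$covariates, collapse = ", "), x$alpha_threshold))
  invisible(x)
}

#' Enumerate the eight model permutations
#'
#' The full 2 x 2 x 2 grid of metric (CE, MBA), form (linear, exponential)
#' and timepoint.
#'
#' @param timepoints timepoint levels (default `c("6h", "24h")`).
#' @param covariates,alpha_threshold passed to [model_spec()].
#' @return named list of 8 [model_spec()] objects (4 if one timepoint).
#' @export
model_specs <- function(timepoints = c("6h", "24h"),
                        covariates = c("sex", "anesthesia", "batch"),
                        alpha_threshold = 0.05) {
  grid <- expand.grid(metric = c("CE", "MBA"),
                      form = c("linear", "exponential"),
                      timepoint = timepoints, stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    model_spec(grid$metric[i], grid$form[i], grid$timepoint[i],
               covariates, alpha_threshold)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Build the design matrix for one model
#'
#' Selects the samples usable by `spec` (matching timepoint; for MBA
#' models, samples with a measured or assigned MBA — treated samples
#' without a paired cavitation recording are excluded), encodes the metric
#' covariate per the model form, and dummy-codes the categorical covariates
#' against the first level in lexicographic order. Covariates with a single
#' level among the selected samples are dropped with a message.
#'
#' @param samples sample metadata data.frame (columns `sample_id`, `sex`,
#'   `anesthesia`, `batch`, `timepoint`, `fus`, `ce`, `mba`).
#' @param spec a [model_spec()].
#' @return list: `design` (numeric matrix with columns `(Intercept)`,
#'   `metric`, dummies), `samples` (the rows used), `dropped_covariates`,
#'   `reference_levels`.
#' @export
build_design <- function(samples, spec) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c("sample_id", "sex", "anesthesia", "batch", "timepoint", "fus",
            "ce", "mba")
  if (!all(need %in% names(samples))) {
    stop_fustx("sample table must have columns: ", paste(need, collapse = ", "))
  }
  metric_col <- if (spec$metric == "CE") samples$ce else samples$mba
  use <- samples$timepoint == spec$timepoint & !is.na(metric_col)
  sub <- samples[use, , drop = FALSE]
  m <- metric_col[use]
  if (any(m < 1)) {
    stop_fustx("metric values below 1 found; untreated samples must be assigned 1")
  }
  x <- if (spec$form == "linear") log(m) else m

  X <- cbind(`(Intercept)` = 1, metric = x)
  dropped <- character()
  refs <- character()
  for (v in spec$covariates) {
    lev <- sort(unique(sub[[v]]))
    if (length(lev) < 2L) {
      dropped <- c(dropped, v)
      next
    }
    refs[v] <- lev[1L]
    f <- factor(sub[[v]], levels = lev)
    d <- stats::model.matrix(~f)[, -1L, drop = FALSE]
    colnames(d) <- paste0(v, lev[-1L])
    X <- cbind(X, d)
  }
  if (length(dropped)) {
    message("covariate(s) with a single level dropped: ",
            paste(dropped, collapse = ", "))
  }
  # an all-untreated subset has a linear-form metric column of exact zeros
  # (ln 1 = 0): the model then reduces to covariates-only rather than being
  # treated as rank deficient
  metric_estimable <- any(X[, "metric"] != 0)
  Xcheck <- if (metric_estimable) X else X[, colnames(X) != "metric",
                                           drop = FALSE]
  qrX <- qr(Xcheck)
  if (qrX$rank < ncol(Xcheck)) {
    aliased <- colnames(Xcheck)[qrX$pivot[seq(qrX$rank + 1L, ncol(Xcheck))]]
    stop_fustx("design matrix is rank deficient; aliased columns: ",
               paste(aliased, collapse = ", "))
  }
  rownames(X) <- sub$sample_id
  list(design = X, samples = sub, dropped_covariates = dropped,
       reference_levels = refs, metric_estimable = metric_estimable)
}

#' Fit one model permutation across all genes
#'
#' Runs the full per-model pipeline on the samples selected by `spec`:
#' median-of-ratios size factors, optional minimum-mean filter, dispersion
#' estimation with trend shrinkage, per-gene NB GLM fits, Wald tests of the
#' metric coefficient, and Benjamini-Hochberg correction across genes.
#'
#' @param counts genes x samples matrix (all samples; columns are subset
#'   internally).
#' @param samples sample metadata data.frame.
#' @param spec a [model_spec()].
#' @param min_mean minimum normalized base mean for a gene to be tested
#'   (default 0 = no filter; filtered genes are omitted from the table).
#' @param sf_method size-factor method, see [size_factors()].
#' @return a `fit_table` data.frame: `gene`, `baseMean`, `coef`, `se`,
#'   `stat`, `pvalue`, `padj`, `converged`, with the spec and design stored
#'   in attributes `spec` and `design_info`.
#' @export
fit_model <- function(counts, samples, spec, min_mean = 0,
                      sf_method = "ratio") {
  counts <- check_counts(counts)
  d <- build_design(samples, spec)
  if (!d$metric_estimable) {
    stop_fustx(sprintf("model %s: metric covariate is identically zero (no treated samples)",
                       spec$name))
  }
  if (nrow(d$design) < 3L) {
    stop_fustx(sprintf("model %s has %d usable samples (< 3)", spec$name,
                       nrow(d$design)))
  }
  sub <- counts[, d$samples$sample_id, drop = FALSE]
  sub <- drop_zero_genes(sub, quiet = TRUE)
  if (nrow(d$design) - ncol(d$design) < 2L) {
    stop_fustx(sprintf("model %s: fewer than 2 residual degrees of freedom",
                       spec$name))
  }
  sf <- size_factors(sub, method = sf_method)
  base_mean <- rowMeans(sweep(sub, 2L, sf, "/"))
  if (min_mean > 0) {
    sub <- sub[base_mean >= min_mean, , drop = FALSE]
    base_mean <- base_mean[base_mean >= min_mean]
  }
  disp <- estimate_dispersions(sub, sf, d$design)

  g <- nrow(sub)
  coef <- se <- rep(NA_real_, g)
  converged <- logical(g)
  for (i in seq_len(g)) {
    f <- fit_gene(sub[i, ], sf, d$design, disp$final[i])
    coef[i] <- f$beta[["metric"]]
    se[i] <- f$se[["metric"]]
    converged[i] <- f$converged
  }
  wt <- wald_test(coef, se, converged)
  tab <- data.frame(gene = rownames(sub), baseMean = base_mean, coef = coef,
                    se = se, stat = wt$stat, pvalue = wt$pvalue,
                    padj = bh_adjust(wt$pvalue), converged = converged,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(tab, "spec") <- spec
  attr(tab, "design_info") <- d[c("dropped_covariates", "reference_levels")]
  attr(tab, "dispersion_trend") <- disp$trend_coef
  class(tab) <- c("fit_table", "data.frame")
  tab
}

#' Run all model permutations
#'
#' Fits every spec in `specs` (by default the eight permutations of form x
#' metric x timepoint) with [fit_model()]. A spec with fewer than 3 usable
#' samples, or any other per-model failure, is skipped with a message; the
#' remaining models proceed.
#'
#' @inheritParams fit_model
#' @param specs list of [model_spec()]s, default [model_specs()].
#' @return named list of `fit_table`s (failed specs omitted).
#' @export
run_models <- function(counts, samples, specs = model_specs(), min_mean = 0,
                       sf_method = "ratio") {
  out <- list()
  for (nm in names(specs)) {
    tab <- tryCatch(fit_model(counts, samples, specs[[nm]],
                              min_mean = min_mean, sf_method = sf_method),
                    error = function(e) {
                      message("model ", nm, " skipped: ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(tab)) out[[nm]] <- tab
  }
  out
}

#' Significant genes of a fit table
#'
#' @param fit a `fit_table` from [fit_model()].
#' @param alpha adjusted-p threshold; defaults to the spec's
#'   `alpha_threshold`.
#' @return character vector of gene ids with `padj < alpha`.
#' @export
significant_genes <- function(fit, alpha = NULL) {
  alpha <- alpha %||% attr(fit, "spec")$alpha_threshold %||% 0.05
  fit$gene[!is.na(fit$padj) & fit$padj < alpha]
}
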