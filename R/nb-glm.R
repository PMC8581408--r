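# Negative-binomial log-link GLM engine: per-gene IRLS fits with a
# sequencing-depth offset, method-of-moments + likelihood dispersion
# estimation with a 1/mu trend and log-normal shrinkage, Wald tests on the
# dose coefficient, and Benjamini-Hochberg correction.

nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-10) {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  }
}

# Cox-Reid adjusted profile log-likelihood for the dispersion: the plain
# profile likelihood at the fitted means is biased low because it ignores
# the degrees of freedom spent on the coefficients; subtracting half the
# log-determinant of the expected information restores near-unbiased
# dispersion estimation.
nb_loglik_cr <- function(y, mu, alpha, X) {
  w <- mu / (1 + alpha * mu)
  ld <- determinant(crossprod(X, X * w), logarithm = TRUE)$modulus
  nb_loglik(y, mu, alpha) - 0.5 * as.numeric(ld)
}

#' Fit one gene's negative-binomial GLM
#'
#' Maximizes the NB log-likelihood with log link and offset `log(sf)` at a
#' fixed dispersion `alpha` by iteratively reweighted least squares
#' (Fisher scoring), declaring convergence when the largest coefficient
#' update falls below `tol`. The returned covariance is the inverse
#' observed information at the optimum, scaled by the residual
#' degrees-of-freedom correction `n / (n - p)`: the plug-in information
#' evaluated at the estimate understates coefficient variance by roughly
#' that factor, and without the correction Wald tests referred to the
#' standard normal are anti-conservative in moderate samples.
#'
#' @param y integer counts for one gene (length = samples).
#' @param sf positive size factors (the offset is `log(sf)`).
#' @param design numeric design matrix (samples x coefficients), full rank.
#' @param alpha NB dispersion (variance `mu + alpha mu^2`); `alpha -> 0`
#'   recovers the Poisson limit.
#' @param tol convergence tolerance on `max |delta beta|`.
#' @param maxit maximum IRLS iterations.
#' @return list: `beta`, `se`, `cov`, `mu` (fitted means), `converged`,
#'   `iter`, `loglik`.
#' @export
fit_gene <- function(y, sf, design, alpha, tol = 1e-6, maxit = 100L) {
  X <- as.matrix(design)
  stopifnot(length(y) == nrow(X), length(sf) == nrow(X), all(sf > 0),
            alpha >= 0)
  off <- log(sf)
  k <- if (alpha > 0) 1 / alpha else Inf
  # initialize from a log-linear least-squares fit on shifted counts
  eta <- log(y + 0.5) - off
  beta <- tryCatch(qr.coef(qr(X), eta), error = function(e) rep(0, ncol(X)))
  beta[is.na(beta)] <- 0
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxit)) {
    iter <- it
    eta <- drop(X %*% beta) + off
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- if (is.finite(k)) mu / (1 + alpha * mu) else mu # expected information
    z <- (eta - off) + (y - mu) / mu
    wX <- X * w
    fit <- tryCatch(solve(crossprod(X, wX), crossprod(wX, z)),
                    error = function(e) NULL)
    if (is.null(fit)) break
    delta <- drop(fit) - beta
    beta <- drop(fit)
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- pmin(pmax(drop(X %*% beta) + off, -30), 30)
  mu <- exp(eta)
  w_obs <- if (is.finite(k)) (y + k) * k * mu / (mu + k)^2 else mu
  info <- crossprod(X, X * w_obs)
  dof_scale <- nrow(X) / max(nrow(X) - ncol(X), 1L)
  cov <- tryCatch(solve(info) * dof_scale, error = function(e) {
    converged <<- FALSE
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- colnames(X)
  names(beta) <- colnames(X)
  list(beta = beta, se = se, cov = cov, mu = mu, converged = converged,
       iter = iter, loglik = nb_loglik(y, mu, alpha))
}

#' Wald test of a fitted coefficient
#'
#' `z = beta / se` referred to the standard normal, two-sided. Returns NA
#' for non-converged fits or non-positive standard errors.
#'
#' @param beta coefficient estimate(s).
#' @param se standard error(s).
#' @param converged logical flag(s); non-converged entries yield NA.
#' @return data.frame with columns `stat` and `pvalue`.
#' @export
wald_test <- function(beta, se, converged = TRUE) {
  ok <- converged & !is.na(se) & se > 0
  stat <- ifelse(ok, beta / se, NA_real_)
  data.frame(stat = stat, pvalue = 2 * stats::pnorm(-abs(stat)))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate correction. `NA` entries are excluded from
#' the adjustment (the effective number of tests is the number of non-NA
#' p values) and preserved in place.
#'
#' @param p numeric p values in `[0, 1]`, NA allowed.
#' @return adjusted p values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_fustx("'p' must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop_fustx("p values outside [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

row_var <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Estimate per-gene NB dispersions with trend shrinkage
#'
#' Three-stage estimator: (1) gene-wise estimates initialized by method of
#' moments on normalized counts and refined by maximizing the per-gene
#' Cox-Reid adjusted NB profile likelihood over `log(alpha)` at the fitted
#' means; (2) a mean-dispersion
#' trend `alpha(mu) = a1 / mu + a0` fitted over genes by least absolute
#' deviations on the log scale, so the trend tracks the median of the
#' right-skewed gene-wise estimates;
#' (3) a final maximum-a-posteriori estimate combining the gene-wise
#' likelihood with a log-normal prior centered on the trend (sd
#' `prior_sdlog` on the natural-log scale). Gene-wise estimates more than
#' `outlier_ratio` times the trend are kept unshrunken, so genuinely
#' overdispersed genes are not pulled toward the trend.
#'
#' @param counts genes x samples matrix (all-zero genes removed).
#' @param sf size factors.
#' @param design design matrix (samples x coefficients).
#' @param prior_sdlog prior sd on `log(alpha)` (default 0.5).
#' @param alpha_min lower bound for all dispersion estimates.
#' @param alpha_max upper bound for gene-wise search.
#' @param outlier_ratio gene-wise/trend ratio above which no shrinkage is
#'   applied.
#' @return list: `raw`, `trend`, `final` (per-gene vectors), `base_mean`,
#'   `trend_coef` (`a0`, `a1`), `fits` (per-gene initial fits reused by the
#'   caller), `outlier` (logical).
#' @export
estimate_dispersions <- function(counts, sf, design, prior_sdlog = 0.5,
                                 alpha_min = 1e-8, alpha_max = 30,
                                 outlier_ratio = 10) {
  counts <- check_counts(counts)
  X <- as.matrix(design)
  if (nrow(X) - ncol(X) < 2L) {
    stop_fustx("need at least 2 residual degrees of freedom")
  }
  g <- nrow(counts)
  norm <- sweep(counts, 2L, sf, "/")
  base_mean <- rowMeans(norm)
  v <- row_var(norm)
  mom <- pmin(pmax((v - base_mean) / base_mean^2, alpha_min), alpha_max)

  lo <- log(alpha_min)
  hi <- log(alpha_max)
  raw <- numeric(g)
  fits <- vector("list", g)
  for (i in seq_len(g)) {
    y <- counts[i, ]
    f <- fit_gene(y, sf, X, mom[i])
    fits[[i]] <- f
    opt <- stats::optimize(function(la) nb_loglik_cr(y, f$mu, exp(la), X),
                           interval = c(lo, hi), maximum = TRUE, tol = 1e-4)
    raw[i] <- exp(opt$maximum)
  }

  trend_fit <- fit_dispersion_trend(raw, base_mean, alpha_min)
  trend <- pmax(trend_fit$a1 / base_mean + trend_fit$a0, alpha_min)

  outlier <- raw > outlier_ratio * trend
  final <- numeric(g)
  for (i in seq_len(g)) {
    if (outlier[i]) {
      final[i] <- raw[i]
      next
    }
    y <- counts[i, ]
    mu <- fits[[i]]$mu
    lt <- log(trend[i])
    opt <- stats::optimize(
      function(la) nb_loglik_cr(y, mu, exp(la), X) -
        (la - lt)^2 / (2 * prior_sdlog^2),
      interval = c(lo, hi), maximum = TRUE, tol = 1e-4)
    final[i] <- exp(opt$maximum)
  }
  list(raw = raw, trend = trend, final = pmax(final, alpha_min),
       base_mean = base_mean, trend_coef = c(a0 = trend_fit$a0,
                                             a1 = trend_fit$a1),
       fits = fits, outlier = outlier)
}

# Median trend of the gene-wise dispersions against 1/mu, fitted by
# iteratively reweighted least squares for the least-absolute-deviations
# criterion on the log scale. Targeting the median rather than the mean
# keeps the trend centred on the underlying alpha(mu) despite the right
# skew of per-gene dispersion estimates. Genes whose gene-wise estimate sat
# on a search bound are excluded; the fit falls back to a constant trend at
# the median dispersion if it degenerates.
fit_dispersion_trend <- function(raw, base_mean, alpha_min,
                                 max_iter = 20L) {
  use <- raw > 10 * alpha_min & raw < 25 & base_mean > 0
  if (sum(use) < 10L) {
    warning("too few informative genes for a dispersion trend; using the median")
    return(list(a0 = max(stats::median(raw), alpha_min), a1 = 0))
  }
  y <- log(raw[use])
  mu <- base_mean[use]
  a0 <- max(stats::median(raw[use]), alpha_min)
  a1 <- a0 # harmless scale-matched start
  par <- log(c(a0, a1))
  obj <- function(p) sum(abs(y - log(exp(p[2]) / mu + exp(p[1]))))
  opt <- tryCatch(
    stats::optim(par, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000L, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt)) {
    warning("dispersion trend fit failed; using the median dispersion")
    return(list(a0 = max(stats::median(raw[use]), alpha_min), a1 = 0))
  }
  list(a0 = max(exp(opt$par[1]), alpha_min), a1 = exp(opt$par[2]))
}
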