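test_that("the model grid enumerates exactly 8 distinct permutations", {
  specs <- model_specs()
  expect_length(specs, 8L)
  combos <- t(vapply(specs, function(s) c(s$metric, s$form, s$timepoint),
                     character(3)))
  expect_equal(nrow(unique(as.data.frame(combos))), 8L)
})

test_that("design encoding honours the untreated baseline", {
  # all-untreated, linear form: metric column identically 0
  s0 <- toy_samples(ce = rep(1, 8), mba = rep(1, 8))
  d0 <- build_design(s0, model_spec("CE", "linear", "6h"))
  expect_true(all(d0$design[, "metric"] == 0))
  # mixed, exponential form: untreated rows carry exactly 1
  s1 <- toy_samples(ce = c(1, 1, 2.5, 4), mba = c(1, 1, 3, 5))
  d1 <- build_design(s1, model_spec("MBA", "exponential", "6h",
                                    covariates = character(0)))
  expect_identical(unname(d1$design[s1$fus == 0, "metric"]), c(1, 1))
})

test_that("a balanced sex-by-anesthesia table yields a full-rank 4-column design", {
  s <- data.frame(sample_id = sprintf("s%d", 1:8),
                  sex = rep(c("M", "F"), 4),
                  anesthesia = rep(c("KA", "KA", "Iso", "Iso"), 2),
                  batch = "b1", timepoint = "6h", fus = 1,
                  ce = seq(1.5, 5, length.out = 8), mba = NA_real_,
                  stringsAsFactors = FALSE)
  d <- build_design(s, model_spec("CE", "linear", "6h",
                                  covariates = c("sex", "anesthesia")))
  expect_equal(ncol(d$design), 4L)
  expect_equal(qr(d$design)$rank, 4L)
  expect_equal(unname(d$reference_levels), c("F", "Iso")) # lexicographic
})

test_that("single-level covariates are dropped and aliasing is reported", {
  s <- toy_samples(ce = c(1, 1, 2, 3, 4, 5), mba = rep(NA_real_, 6))
  s$batch <- "b1"
  expect_message(build_design(s, model_spec("CE", "linear", "6h")), "batch")
  s2 <- s
  s2$sex <- c("M", "F", "M", "F", "M", "F")
  s2$anesthesia <- c("KA", "Iso", "KA", "Iso", "KA", "Iso") # aliased with sex
  expect_error(suppressMessages(
    build_design(s2, model_spec("CE", "linear", "6h"))), "aliased")
})

test_that("intercept-only fit recovers the closed-form log mean", {
  y <- rep(7L, 10)
  X <- matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_gene(y, rep(1, 10), X, alpha = 1e-12)
  expect_equal(unname(f$beta), log(7), tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("the Poisson limit agrees with the stats::glm oracle", {
  set.seed(51)
  n <- 40L
  x <- c(rep(0, 20), runif(20, 0.3, 1.5))
  sf <- exp(rnorm(n, 0, 0.1))
  X <- cbind(`(Intercept)` = 1, metric = x)
  for (i in 1:50) {
    y <- rpois(n, lambda = sf * exp(3 + 0.5 * x))
    f <- fit_gene(y, sf, X, alpha = 1e-12)
    oracle <- glm(y ~ x, family = poisson, offset = log(sf))
    expect_equal(unname(f$beta), unname(coef(oracle)), tolerance = 1e-4)
  }
})

test_that("fixed-dispersion fits agree with the MASS negative-binomial oracle", {
  skip_if_not_installed("MASS")
  set.seed(55)
  n <- 60L
  x <- c(rep(0, 30), runif(30, 0.2, 1.8))
  sf <- exp(rnorm(n, 0, 0.1))
  X <- cbind(`(Intercept)` = 1, metric = x)
  for (alpha in c(0.02, 0.1, 0.5)) {
    y <- rnbinom(n, mu = sf * exp(3.5 + 0.6 * x), size = 1 / alpha)
    f <- fit_gene(y, sf, X, alpha)
    oracle <- glm(y ~ x, family = MASS::negative.binomial(theta = 1 / alpha),
                  offset = log(sf))
    expect_equal(unname(f$beta), unname(coef(oracle)), tolerance = 1e-5)
  }
})

test_that("the size-factor offset enters the model correctly", {
  set.seed(61)
  n <- 20L
  x <- runif(n, 0, 2)
  X <- cbind(`(Intercept)` = 1, metric = x)
  y <- rnbinom(n, mu = 50 * exp(0.4 * x), size = 10)
  sf <- exp(rnorm(n, 0, 0.2))
  f1 <- fit_gene(y, sf, X, alpha = 0.1)
  # rescaling every factor by a constant shifts only the intercept, exactly
  f2 <- fit_gene(y, sf * 5, X, alpha = 0.1)
  expect_equal(f2$beta[["metric"]], f1$beta[["metric"]], tolerance = 1e-6)
  expect_equal(f2$beta[["(Intercept)"]], f1$beta[["(Intercept)"]] - log(5),
               tolerance = 1e-6)
  # jointly scaling one sample's counts and factor moves the estimate only
  # within the likelihood's information about that observation
  y3 <- y
  y3[3] <- y[3] * 3L
  sf3 <- sf
  sf3[3] <- sf[3] * 3
  f3 <- fit_gene(y3, sf3, X, alpha = 0.1)
  expect_equal(f3$beta, f1$beta, tolerance = 1e-2)
})

test_that("single-gene dispersion likelihood matches a grid-search oracle", {
  set.seed(71)
  n <- 60L
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  sf <- rep(1, n)
  y <- rnbinom(n, mu = 80, size = 1 / 0.2)
  f <- fit_gene(y, sf, X, alpha = 0.2)
  # oracle: dense grid over ln alpha of the same CR-adjusted objective
  grid <- seq(log(1e-6), log(5), length.out = 4000)
  obj <- vapply(grid, function(la) {
    a <- exp(la)
    w <- f$mu / (1 + a * f$mu)
    sum(dnbinom(y, size = 1 / a, mu = f$mu, log = TRUE)) -
      0.5 * as.numeric(determinant(crossprod(X, X * w))$modulus)
  }, numeric(1))
  grid_opt <- grid[which.max(obj)]
  opt <- optimize(function(la) {
    a <- exp(la)
    w <- f$mu / (1 + a * f$mu)
    sum(dnbinom(y, size = 1 / a, mu = f$mu, log = TRUE)) -
      0.5 * as.numeric(determinant(crossprod(X, X * w))$modulus)
  }, c(log(1e-8), log(30)), maximum = TRUE, tol = 1e-6)
  expect_equal(opt$maximum, grid_opt, tolerance = 1e-2)
  # and the packaged estimator lands on the same optimum
  counts <- matrix(y, 1, n, dimnames = list("g1", sprintf("s%02d", 1:n)))
  disp <- suppressWarnings(estimate_dispersions(counts, sf, X))
  expect_equal(log(disp$raw), opt$maximum, tolerance = 1e-3)
})

test_that("dispersion estimation shrinks Poisson data to near zero", {
  set.seed(81)
  n <- 100L
  g <- 150L
  counts <- matrix(rpois(g * n, lambda = rep(exp(rnorm(g, log(80), 0.5)), n)),
                   nrow = g, dimnames = list(sprintf("g%03d", 1:g),
                                             sprintf("s%03d", 1:n)))
  counts <- counts[rowSums(counts) > 0, ]
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  disp <- suppressWarnings(estimate_dispersions(counts, rep(1, n), X))
  expect_lte(median(disp$final), 0.01)
})

test_that("the dispersion trend parameters are recovered from synthetic data", {
  cfg <- sim_config(n_genes = 2000L, timepoints = "6h", seed = 91L)
  met <- simulate_metrics(cfg)
  counts <- simulate_counts(met$truth, cfg, met$samples)
  counts <- drop_zero_genes(counts, quiet = TRUE)
  d <- build_design(met$samples, model_spec("CE", "linear", "6h"))
  disp <- estimate_dispersions(counts, size_factors(counts), d$design)
  expect_lt(abs(disp$trend_coef[["a0"]] - 0.05) / 0.05, 0.3)
  expect_lt(abs(disp$trend_coef[["a1"]] - 3) / 3, 0.3)
})

test_that("wald test maps coefficients to two-sided normal p values", {
  wt <- wald_test(c(0, 1.959964, 3), c(1, 1, NA), c(TRUE, TRUE, TRUE))
  expect_equal(wt$pvalue[1], 1)
  expect_equal(wt$pvalue[2], 0.05, tolerance = 1e-6)
  expect_true(is.na(wt$pvalue[3]))
  expect_true(is.na(wald_test(2, 1, FALSE)$pvalue))
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.42), 0.42)
  # NA excluded but preserved
  p <- c(0.01, NA, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), c(0.04, NA, 0.04, 0.04, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("BH is order-equivariant, monotone, and never below the raw p", {
  set.seed(101)
  p <- runif(30)^2
  adj <- bh_adjust(p)
  perm <- sample(30)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # step-up monotonicity: adjusted values ordered like the raw ones
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= 0))
})

test_that("null fits give approximately uniform p values", {
  # a stochastic property: require uniformity to survive a 1% KS test in
  # the clear majority of independent replicates
  ks_p <- vapply(c(111L, 112L, 113L), function(s) {
    cfg <- sim_config(n_genes = 800L, frac_nonnull = 0, timepoints = "6h",
                      seed = s)
    met <- simulate_metrics(cfg)
    counts <- simulate_counts(met$truth, cfg, met$samples)
    ft <- fit_model(counts, met$samples, model_spec("CE", "linear", "6h"))
    suppressWarnings(ks.test(ft$pvalue[!is.na(ft$pvalue)], "punif"))$p.value
  }, numeric(1))
  expect_gte(sum(ks_p > 0.01), 2L)
})

test_that("the matched model recovers the most true positives", {
  hits <- matrix(0, 3, 8)
  for (s in 1:3) {
    cfg <- sim_config(n_genes = 400L, frac_nonnull = 0.15, metric_mix = 1,
                      form_mix = 0, timepoints = c("6h", "24h"), seed = 120L + s)
    met <- simulate_metrics(cfg)
    # concentrate true effects at 6h samples only by restricting non-null
    # genes to the exponential/CE configuration the matched model fits
    counts <- simulate_counts(met$truth, cfg, met$samples)
    fits <- suppressMessages(run_models(counts, met$samples, model_specs()))
    nn_genes <- met$truth$genes$gene_id[met$truth$genes$nonnull]
    hits[s, ] <- vapply(fits, function(f) {
      length(intersect(significant_genes(f), nn_genes))
    }, numeric(1))
  }
  colnames(hits) <- names(model_specs())
  avg <- colMeans(hits)
  matched <- avg[c("CE_exponential_6h", "CE_exponential_24h")]
  unmatched <- avg[c("MBA_linear_6h", "MBA_linear_24h",
                     "MBA_exponential_6h", "MBA_exponential_24h")]
  expect_gt(max(matched), max(unmatched))
})

test_that("a model with too few samples is skipped while others proceed", {
  cfg <- sim_config(n_samples = 30L, n_genes = 60L, n_fus_positive = 10L,
                    n_mba_measured = 8L, timepoints = "6h", seed = 131L)
  met <- simulate_metrics(cfg)
  counts <- simulate_counts(met$truth, cfg, met$samples)
  specs <- model_specs(timepoints = c("6h", "24h"))
  fits <- suppressMessages(run_models(counts, met$samples, specs))
  expect_true(all(grepl("_6h$", names(fits))))
  expect_length(fits, 4L)
})
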