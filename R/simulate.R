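#' Configuration for the synthetic FUS-BBBD study generator
#'
#' Describes a synthetic version of the aggregated study design: `n_samples`
#' transcriptomes of which `n_fus_positive` are FUS-treated with contrast
#' enhancement (CE) measured, `n_mba_measured` of those also carrying a
#' paired microbubble-activation (MBA) measurement, and the remainder
#' FUS-negative controls (assigned CE = MBA = 1). Treated samples draw
#' correlated (CE, MBA) pairs; a configurable fraction of genes responds to
#' one metric through a linear or exponential dose form on the log-mean of
#' negative-binomial counts.
#'
#' @param n_samples total number of samples (default 75).
#' @param n_genes number of genes (default 2000; a desk-scale stand-in for a
#'   genome-wide matrix).
#' @param frac_nonnull fraction of genes with a true metric effect.
#' @param effect_size_log magnitude of the true per-gene metric coefficient
#'   on the log scale (sign randomized per gene).
#' @param ce_mba_r2 target squared correlation between the raw CE and MBA
#'   values of treated samples (expected OLS R-squared of MBA on CE);
#'   must lie in `[0, 1)`. Default 0.59.
#' @param n_fus_positive number of FUS-treated samples (default 27).
#' @param n_mba_measured number of treated samples whose MBA is observed in
#'   the metadata (default 18); the rest have `NA` MBA but a ground-truth
#'   value.
#' @param dispersion_trend named vector `c(a0 = , a1 = )` of the dispersion
#'   mean-trend `alpha(mu) = a1 / mu + a0` (both `>= 0`).
#' @param dispersion_jitter_sdlog log-normal jitter sd around the trend.
#' @param covariate_effects named list of per-gene coefficient sds (log
#'   scale) for `sex`, `anesthesia`, `batch`.
#' @param timepoints character vector of timepoints to assign; samples are
#'   split evenly across it. Use a single value to put all samples at one
#'   timepoint.
#' @param baseline_meanlog,baseline_sdlog normal parameters for per-gene
#'   baseline log-means.
#' @param libsize_sdlog log-normal sd of true per-sample library-size factors.
#' @param ce_meanlog,ce_sdlog,mba_meanlog,mba_sdlog parameters of the
#'   shifted log-normal marginals of treated-sample CE and MBA
#'   (`metric = 1 + lognormal`), guaranteeing all metric values exceed 1 so
#'   the log transform used by the linear model form is always defined.
#' @param form_mix fraction of non-null genes using the linear form (the
#'   rest are exponential).
#' @param metric_mix fraction of non-null genes tied to CE (the rest to MBA).
#' @param seed integer seed governing all draws.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 75L, n_genes = 2000L, frac_nonnull = 0.1,
                       effect_size_log = 1, ce_mba_r2 = 0.59,
                       n_fus_positive = 27L, n_mba_measured = 18L,
                       dispersion_trend = c(a0 = 0.05, a1 = 3),
                       dispersion_jitter_sdlog = 0.3,
                       covariate_effects = list(sex = 0.1, anesthesia = 0.2,
                                                batch = 0.1),
                       timepoints = c("6h", "24h"),
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       libsize_sdlog = 0.15,
                       ce_meanlog = -0.1, ce_sdlog = 0.5,
                       mba_meanlog = 0.3, mba_sdlog = 0.5,
                       form_mix = 0.5, metric_mix = 0.5, seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples", lower = 1L)
  n_genes <- check_count(n_genes, "n_genes", lower = 1L)
  check_number(frac_nonnull, "frac_nonnull", lower = 0, upper = 1)
  check_number(effect_size_log, "effect_size_log")
  if (!is.numeric(ce_mba_r2) || length(ce_mba_r2) != 1L || is.na(ce_mba_r2) ||
      ce_mba_r2 < 0 || ce_mba_r2 >= 1) {
    stop_fustx("'ce_mba_r2' must lie in [0, 1)")
  }
  n_fus_positive <- check_count(n_fus_positive, "n_fus_positive", lower = 0L)
  if (n_fus_positive > n_samples) stop_fustx("n_fus_positive exceeds n_samples")
  n_mba_measured <- check_count(n_mba_measured, "n_mba_measured", lower = 0L)
  if (n_mba_measured > n_fus_positive) {
    stop_fustx("n_mba_measured exceeds n_fus_positive")
  }
  stopifnot(all(c("a0", "a1") %in% names(dispersion_trend)))
  if (any(dispersion_trend < 0)) stop_fustx("dispersion trend parameters must be >= 0")
  check_number(form_mix, "form_mix", lower = 0, upper = 1)
  check_number(metric_mix, "metric_mix", lower = 0, upper = 1)
  seed <- check_count(seed, "seed")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: %d samples (%d FUS+, %d with MBA), %d genes, ",
    "%.0f%% non-null @ |beta1| = %g, target CE~MBA R^2 = %g, seed %d\n"),
    x$n_samples, x$n_fus_positive, x$n_mba_measured, x$n_genes,
    100 * x$frac_nonnull, x$effect_size_log, x$ce_mba_r2, x$seed))
  invisible(x)
}

# Latent-scale correlation that yields a target Pearson correlation between
# two (shifted) log-normals: if (Z1, Z2) are standard bivariate normal with
# correlation rho and X_i = exp(m_i + s_i Z_i), then
#   cor(X1, X2) = (exp(rho s1 s2) - 1) / sqrt((exp(s1^2)-1)(exp(s2^2)-1)),
# and adding the constant 1 shift changes nothing. Inverting for rho gives
# the latent correlation to use.
latent_rho_for_target <- function(r_target, s1, s2) {
  if (r_target == 0) return(0)
  rho <- log(1 + r_target * sqrt(expm1(s1^2) * expm1(s2^2))) / (s1 * s2)
  if (rho > 1) {
    stop_fustx(sprintf(
      "target correlation %.3f is not attainable with sdlogs %.3g/%.3g",
      r_target, s1, s2))
  }
  rho
}

#' Simulate sample metadata, correlated BBBD metrics, and gene ground truth
#'
#' Generates the per-sample table (sex, anesthesia, batch, timepoint, FUS
#' status, CE, MBA) and the full ground truth used by [simulate_counts()].
#' FUS-negative samples are assigned CE = MBA = 1 exactly (the untreated
#' baseline, so the log-scale covariate of the linear model form is 0 for
#' them). Treated samples draw `(ln(CE - 1), ln(MBA - 1))` from a bivariate
#' normal whose latent correlation is solved analytically so that the
#' expected squared Pearson correlation of the raw metrics — hence the
#' expected OLS R-squared of a regression of MBA on CE — equals
#' `cfg$ce_mba_r2`.
#'
#' @param cfg a [sim_config()].
#' @return a list with `samples` (data.frame: sample_id, sex, anesthesia,
#'   batch, timepoint, fus, ce, mba; `mba` is `NA` for treated samples
#'   without a PCD measurement) and `truth` (sample-level true metrics and
#'   size factors plus the per-gene table consumed by [simulate_counts()]).
#' @export
simulate_metrics <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  npos <- cfg$n_fus_positive
  fus <- c(rep(1L, npos), rep(0L, n - npos))

  rho <- latent_rho_for_target(sqrt(cfg$ce_mba_r2), cfg$ce_sdlog, cfg$mba_sdlog)
  z1 <- stats::rnorm(npos)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(npos)
  ce_true <- rep(1, n)
  mba_true <- rep(1, n)
  if (npos > 0L) {
    ce_true[seq_len(npos)] <- 1 + exp(cfg$ce_meanlog + cfg$ce_sdlog * z1)
    mba_true[seq_len(npos)] <- 1 + exp(cfg$mba_meanlog + cfg$mba_sdlog * z2)
  }
  mba_obs <- mba_true
  if (npos > cfg$n_mba_measured) {
    mba_obs[seq(cfg$n_mba_measured + 1L, npos)] <- NA_real_
  }

  # balanced, seed-shuffled covariate assignment
  lev <- function(levels) sample(rep_len(levels, n))
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    sex = lev(c("M", "F")),
    anesthesia = lev(c("KA", "Iso")),
    batch = lev(c("b1", "b2", "b3")),
    timepoint = lev(cfg$timepoints),
    fus = fus,
    ce = ce_true,
    mba = mba_obs,
    stringsAsFactors = FALSE
  )

  g <- cfg$n_genes
  n_nonnull <- round(cfg$frac_nonnull * g)
  nonnull <- logical(g)
  nonnull[sample.int(g, n_nonnull)] <- TRUE
  metric <- ifelse(stats::runif(g) < cfg$metric_mix, "CE", "MBA")
  form <- ifelse(stats::runif(g) < cfg$form_mix, "linear", "exponential")
  sign <- sample(c(-1, 1), g, replace = TRUE)
  beta1 <- ifelse(nonnull, sign * cfg$effect_size_log, 0)
  beta0 <- stats::rnorm(g, cfg$baseline_meanlog, cfg$baseline_sdlog)
  mu0 <- exp(beta0)
  a <- cfg$dispersion_trend
  alpha <- (a[["a1"]] / mu0 + a[["a0"]]) *
    exp(stats::rnorm(g, 0, cfg$dispersion_jitter_sdlog))
  genes <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(g)),
    nonnull = nonnull,
    metric = metric,
    form = form,
    beta0 = beta0,
    beta_ce = ifelse(metric == "CE", beta1, 0),
    beta_mba = ifelse(metric == "MBA", beta1, 0),
    beta_sex = stats::rnorm(g, 0, cfg$covariate_effects$sex),
    beta_anesthesia = stats::rnorm(g, 0, cfg$covariate_effects$anesthesia),
    beta_batch = stats::rnorm(g, 0, cfg$covariate_effects$batch),
    dispersion = as.numeric(alpha),
    stringsAsFactors = FALSE
  )
  size_factors_true <- exp(stats::rnorm(n, 0, cfg$libsize_sdlog))
  names(size_factors_true) <- samples$sample_id

  list(samples = samples,
       truth = list(genes = genes, ce_true = ce_true, mba_true = mba_true,
                    size_factors_true = size_factors_true))
}

#' Simulate a negative-binomial count matrix from ground truth
#'
#' Draws gene-by-sample counts `K_ij ~ NB(mean = s_j q_ij, dispersion
#' alpha_i)` with `ln q_ij = beta0_i + beta1_i x_ij + covariate offsets`,
#' where `x_ij` is the raw metric (exponential form) or its natural log
#' (linear form). Counts are drawn gene by gene with `rnbinom(size =
#' 1/alpha)`, after `set.seed(cfg$seed + 1L)`, so a fixed configuration is
#' bit-reproducible. Log-means above `log(1e8)` are clamped with a warning.
#'
#' @param truth the `truth` element returned by [simulate_metrics()].
#' @param cfg the same [sim_config()].
#' @param samples the sample table from [simulate_metrics()]; defaults to
#'   regenerating it from `cfg` (identical by determinism).
#' @return integer matrix, genes x samples, with dimnames.
#' @export
simulate_counts <- function(truth, cfg, samples = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(samples)) samples <- simulate_metrics(cfg)$samples
  genes <- truth$genes
  n <- nrow(samples)
  g <- nrow(genes)
  offs <- genes$beta_sex %o% as.numeric(samples$sex == "F") +
    genes$beta_anesthesia %o% as.numeric(samples$anesthesia == "Iso") +
    genes$beta_batch %o% (as.numeric(factor(samples$batch)) - 1)
  x_lin <- rbind(CE = log(truth$ce_true), MBA = log(truth$mba_true))
  x_exp <- rbind(CE = truth$ce_true, MBA = truth$mba_true)
  sf <- truth$size_factors_true

  set.seed(cfg$seed + 1L)
  counts <- matrix(0L, nrow = g, ncol = n,
                   dimnames = list(genes$gene_id, samples$sample_id))
  clamped <- FALSE
  beta1 <- genes$beta_ce + genes$beta_mba
  for (i in seq_len(g)) {
    x <- if (genes$form[i] == "linear") x_lin[genes$metric[i], ]
         else x_exp[genes$metric[i], ]
    log_mu <- log(sf) + genes$beta0[i] + beta1[i] * x + offs[i, ]
    over <- log_mu > log(1e8)
    if (any(over)) {
      clamped <- TRUE
      log_mu[over] <- log(1e8)
    }
    counts[i, ] <- stats::rnbinom(n, size = 1 / genes$dispersion[i],
                                  mu = exp(log_mu))
  }
  if (clamped) warning("some simulated means exceeded 1e8 and were clamped")
  counts
}

#' Simulate per-pulse hydrophone waveforms with a controllable harmonic tone
#'
#' Emits `n_pulses` segments of a continuous sinusoid at the second-harmonic
#' frequency plus independent white Gaussian noise, emulating a passive
#' cavitation detection session in which harmonic emission strength scales
#' with microbubble activation. Segments of one continuous phase are used so
#' the appended series carries a single coherent tone.
#'
#' @param harmonic_amp amplitude of the harmonic tone (0 for noise-only).
#' @param noise_sd white-noise standard deviation.
#' @param fs sampling rate (Hz); must exceed twice the tone frequency.
#' @param n_pulses,pulse_len number and length of pulses; their product sets
#'   the appended-FFT bin width `fs / (n_pulses * pulse_len)`, which must be
#'   at most 40 Hz so a 200 Hz band holds at least 5 bins.
#' @param seed integer seed for the noise.
#' @param f0 tone frequency (Hz); defaults to the 2.22 MHz second harmonic.
#' @return a [waveform_record()].
#' @export
simulate_waveforms <- function(harmonic_amp, noise_sd = 1, fs = 1e7,
                               n_pulses = 50L, pulse_len = 5000L, seed = 1L,
                               f0 = 2.22e6) {
  check_number(harmonic_amp, "harmonic_amp", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  n_pulses <- check_count(n_pulses, "n_pulses", lower = 1L)
  pulse_len <- check_count(pulse_len, "pulse_len", lower = 1L)
  if (fs <= 2 * f0) {
    stop_fustx(sprintf("fs = %g Hz violates Nyquist for a %g Hz tone (need fs > %g)",
                       fs, f0, 2 * f0))
  }
  total <- n_pulses * pulse_len
  if (fs / total > 40) {
    stop_fustx(sprintf(paste0(
      "appended-FFT bin width %.3g Hz exceeds 40 Hz: need n_pulses * pulse_len ",
      ">= %d total samples at fs = %g Hz"), fs / total, ceiling(fs / 40), fs))
  }
  set.seed(seed)
  t <- (seq_len(total) - 1) / fs
  signal <- harmonic_amp * sin(2 * pi * f0 * t)
  noise <- stats::rnorm(total, 0, noise_sd)
  x <- signal + noise
  pulses <- split(x, rep(seq_len(n_pulses), each = pulse_len))
  names(pulses) <- NULL
  waveform_record(pulses, fs)
}
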