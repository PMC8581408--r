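# Independent oracles kept deliberately naive: each recomputes a quantity by
# direct definition, never by calling the implementation under test.

# Direct O(n^2) DFT, one-sided magnitudes scaled like appended_spectrum.
direct_dft_amp <- function(x) {
  n <- length(x)
  nh <- n %/% 2 + 1L
  idx <- 0:(n - 1)
  amp <- vapply(0:(nh - 1), function(k) {
    Mod(sum(x * exp(-2i * pi * k * idx / n)))
  }, numeric(1)) * (2 / n)
  amp[1L] <- amp[1L] / 2
  if (n %% 2L == 0L) amp[nh] <- amp[nh] / 2
  amp
}

# Median-of-ratios size factors by literal definition, loops and all.
mor_oracle <- function(counts) {
  geo <- apply(counts, 1L, function(r) exp(mean(log(r))))
  ok <- is.finite(geo) & geo > 0
  sapply(seq_len(ncol(counts)), function(j) {
    median(counts[ok, j] / geo[ok])
  })
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of an
# N-gene universe and count those overlapping the set in >= k genes.
hyper_enum_oracle <- function(universe, set, query) {
  n <- length(query)
  k <- length(intersect(query, set))
  draws <- combn(universe, n)
  hits <- apply(draws, 2L, function(d) length(intersect(d, set)) >= k)
  mean(hits)
}

# Minimal fit_table-shaped data.frame for pooling tests.
fake_fit <- function(genes, padj, coef) {
  tab <- data.frame(gene = genes, baseMean = 10, coef = coef, se = 1,
                    stat = coef, pvalue = padj, padj = padj,
                    converged = TRUE, stringsAsFactors = FALSE)
  class(tab) <- c("fit_table", "data.frame")
  tab
}

# Small deterministic count matrix.
tiny_counts <- function(g = 50L, n = 6L, seed = 42L) {
  set.seed(seed)
  m <- matrix(rnbinom(g * n, mu = 50, size = 5), nrow = g,
              dimnames = list(sprintf("g%03d", seq_len(g)),
                              sprintf("s%02d", seq_len(n))))
  storage.mode(m) <- "integer"
  m[rowSums(m) > 0, , drop = FALSE]
}

# Sample table with n samples at one timepoint, metrics given. Covariate
# cycles have coprime periods so the dummies are not mutually aliased.
toy_samples <- function(ce, mba, timepoint = "6h") {
  n <- length(ce)
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             sex = rep_len(c("M", "F"), n),
             anesthesia = rep_len(c("KA", "KA", "Iso"), n),
             batch = rep_len(c("b1", "b2", "b3", "b1", "b3"), n),
             timepoint = timepoint,
             fus = as.integer(ce != 1),
             ce = ce, mba = mba, stringsAsFactors = FALSE)
}
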