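# fustx

Regression of brain gene expression on continuous metrics of
focused-ultrasound (FUS) blood–brain barrier disruption.

## The problem

FUS with circulating microbubbles transiently opens the blood–brain barrier
(BBB), exposing brain tissue to two distinct stimuli: the **mechanical**
force of microbubbles oscillating in vessels, proxied by microbubble
activation (**MBA**, a harmonic acoustic-emission metric from passive
cavitation detection), and the **biochemical** exposure to plasma, proxied
by MR contrast enhancement (**CE**). `fustx` is for researchers asking
which transcriptional programs in post-FUS bulk RNA-seq track each
stimulus: it regresses per-gene counts on MBA or CE as *continuous* dose
covariates, controlling for sex, anesthesia, and sequencing batch.

## The model

Counts follow a negative binomial GLM with log link and a sequencing-depth
offset:

K_ij ~ NB(mu_ij, alpha_i),  mu_ij = s_j q_ij,
log q_ij = beta_0i + beta_1i x_j + covariate terms

with median-of-ratios size factors s_j and variance mu + alpha mu².
Eight models are fitted per gene — every permutation of dose form
(linear: x = ln(metric); exponential: x = metric), metric (CE or MBA),
and timepoint (6 h or 24 h) — with untreated samples assigned metric value
1, so the linear-form covariate is exactly 0 at baseline. Dispersions are
estimated gene-wise by Cox–Reid adjusted profile likelihood, trended
against 1/mu, and shrunk toward the trend under a log-normal prior. The
metric coefficient is Wald-tested (standard normal, two-sided) with
Benjamini–Hochberg correction per model; significant genes from each
linear/exponential pair merge by union into four signed pools whose
overlaps are accounted exclusively (UpSet-style), and each signed pool is
tested for gene-set over-representation by the upper-tail hypergeometric
probability against a GMT collection, with Jaccard-based redundancy
pruning.

The MBA metric itself is also implemented: pulses of a cavitation session
are appended, Fourier-transformed, and MBA is the ratio of the mean top-5
peak amplitude in a 200 Hz band at the second harmonic (2.22 MHz) to the
same statistic in a broadband reference band.

A synthetic-data module emulates the full study design — 75 transcriptomes
(27 FUS-treated with CE, 18 of those with MBA, 50 controls), correlated
CE/MBA pairs hitting a configurable R² (0.59 by default), NB counts with
known effects, and tone-plus-noise cavitation waveforms — so the whole
pipeline runs and is tested without any external data.

## Worked example

```r
library(fustx)

cfg <- sim_config(seed = 1L)          # the emulated study design
met <- simulate_metrics(cfg)
counts <- simulate_counts(met$truth, cfg, met$samples)

collinearity(met$samples)
#> MBA ~ CE over 18 samples: R^2 = 0.688, VIF = 3.21, slope = 1.33

rec <- simulate_waveforms(harmonic_amp = 3, noise_sd = 1, seed = 1L)
compute_mba(rec, spectral_config(reference_center = 3.5e6))
#> MBA = 114.3 (harmonic 0.6049 / reference 0.005293; 5/5 band bins)

fits <- run_models(counts, met$samples, model_specs())
sapply(fits, function(f) length(significant_genes(f)))
#>        CE_linear_6h       MBA_linear_6h   CE_exponential_6h  MBA_exponential_6h
#>                 203                 190                 202                 190
#>       CE_linear_24h      MBA_linear_24h  CE_exponential_24h MBA_exponential_24h
#>                 199                 194                 198                 192

pools <- make_pools(fits)
head(upset_intersections(pools, "+"), 4)[, 1:3]
#>                        subset degree exclusive_count
#> 1 CE_6h&MBA_6h&CE_24h&MBA_24h      4              85
#> 2                       CE_6h      1               3
#> 3                      CE_24h      1               1
#> 4              CE_24h&MBA_24h      2               1
```

Reading the output: the collinearity report shows the simulated metrics are
correlated but far from collinear (VIF well below 5), so both can enter as
predictors; the MBA of 114 reflects a strong injected harmonic over the
noise floor (noise-only records score ≈ 1); each of the eight models calls
roughly the simulated 10% of genes significant; and because simulated
effects here persist across both timepoints, most pool members land in the
all-four-pools intersection bin, with small pool-specific remainders.

A single call runs everything and writes TSV/JSON outputs with provenance
headers:

```r
run_pipeline(pipeline_config(out_dir = "out", sim = sim_config(seed = 1L),
                             seed = 1L))
```

or from a shell via `inst/scripts/run_pipeline.R --config cfg.yaml`.

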