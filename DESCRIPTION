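Package: fustx
Title: Regression of Brain Gene Expression on Focused-Ultrasound Blood-Brain
    Barrier Disruption Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate bulk RNA-seq gene expression to two continuous
    measures of focused-ultrasound (FUS) blood-brain-barrier disruption:
    microbubble activation (MBA), a harmonic-emission metric computed from
    passive cavitation detection waveforms, and MR contrast enhancement (CE).
    Provides the MBA spectral metric, median-of-ratios normalization with
    PCA and collinearity diagnostics, a per-gene negative-binomial GLM
    engine with trended dispersion shrinkage fitting eight model
    permutations (linear/exponential form x CE/MBA x 6h/24h) with
    categorical confounder control and Wald tests under Benjamini-Hochberg
    correction, signed union pooling with exclusive (UpSet) intersection
    accounting, hypergeometric over-representation analysis against GMT
    gene-set collections with overlap-based redundancy pruning, and a
    synthetic-data module that emulates the full study design so every
    stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    yaml
Config/testthat/edition: 3
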