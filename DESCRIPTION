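Package: cnscreen
Title: Analysis of Pooled In Vivo CRISPR Screens for T Cell Migration to the CNS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of genome-wide pooled CRISPR knockout
    screens that read out autoreactive T cell migration from blood into
    central nervous system compartments. Provides screen-design arithmetic
    (coverage, multiplicity of infection), low-count filtering,
    median-of-ratios normalization with a per-sgRNA geometric-mean
    reference, a negative-binomial sgRNA-level differential-abundance test
    with a mean-variance trend fitted on non-targeting controls,
    alpha-robust-rank-aggregation gene scoring with a permutation null,
    a non-targeting pseudo-gene resampling null, tiered candidate
    selection and facilitator/brake essentiality calling, blood-normalized
    flow-cytometry migration-ratio statistics with two-stage FDR control,
    and TCR clonal-overlap migration-propensity analysis for paired
    blood/CSF single-cell data. A synthetic-data module simulates every
    input with known ground truth, including compartment migration
    bottlenecks, overdispersed sequencing counts, binomial flow counts and
    participant-level clone structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    DESeq2,
    SummarizedExperiment
Config/testthat/edition: 3
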