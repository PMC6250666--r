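Package: nephroQTL
Title: Kidney cis-eQTL Meta-Analysis, Colocalisation and Mendelian
    Randomisation Toolkit
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for two-cohort kidney cis-eQTL studies:
    genotype/sample/gene quality control, robust expression normalisation
    (log-TPM, median-target quantile normalisation, robust outlier
    imputation, rank-based inverse normal transform), hidden-factor and
    genotype principal-component estimation, per-study cis-eQTL regression
    with fixed-effect inverse-variance meta-analysis, permutation-calibrated
    eGene calling with Storey q-values and per-gene nominal thresholds,
    LD-proxy expansion and matched-SNP enrichment, regulatory trait
    concordance (RTC) colocalisation scoring, two-sample summary-data
    Mendelian randomisation (robust IVW, penalised weighted median, robust
    MR-Egger) with sensitivity analyses, and cross-study
    expression-phenotype meta-analysis (Stouffer weighted Z, Olkin-Pratt).
    Ships a synthetic two-cohort data generator with known ground truth so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
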