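Package: tmbcal
Title: Probabilistic Calibration of Panel-Derived Tumor Mutational Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates gene-panel tumor mutational burden (TMB) to exome-wide
    TMB with a mixture density network that maps per-megabase panel mutation
    counts (nonsynonymous, all, hotspot) and genetic ancestry to the parameters
    of a mixture of log-normal distributions over exomic TMB. Provides
    MAF/BED/VCF-style readers, dinucleotide merging and footprint arithmetic,
    construction of labeled tumor-only cohorts by spiking germline variants
    into somatic profiles under permissive or stringent population-frequency
    filtering, uncertainty-aware tripartite stratification at clinical TMB
    thresholds with NPV/PPV reporting, cross-validated evaluation with
    calibration diagnostics, and a synthetic cohort simulator with nonlinear
    panel bias, heteroscedastic error and ancestry-dependent private germline
    contamination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
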