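Package: mloymr
Title: Mosaic Loss of Chromosome Y Calling and Sex-Stratified Mendelian
    Randomisation for Alzheimer's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting mosaic loss of chromosome Y (mLOY) from
    SNP-array intensity data (mLRR-Y against the trimmed autosomal mean,
    PAR1 B-deviation, positive-side 99% threshold calling with randomised
    batch splitting), for building an autosomal polygenic instrument of
    mLOY liability from published weights, and for the downstream
    sex- and age-stratified association suite: logistic case-control
    models, Cox models of phenoconversion from mild cognitive impairment,
    fixed-effect inverse-variance meta-analysis, CSF biomarker regressions
    and a proteome-wide scan with genomic-control inflation and FDR
    control. A synthetic-cohort generator reproducing the statistical
    structure of an ageing case-control study (age-dependent mLOY
    prevalence, polygenic liability, male-specific conversion hazards,
    tau-correlated protein panels) makes the whole pipeline testable
    end-to-end without individual-level data access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    optparse
Config/testthat/edition: 3
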