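Package: exocohort
Title: Exome Cohort Characterization: Variant QC, LOF Burden Scans,
    Carrier Saturation and Penetrance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing rare coding variation in large
    sequenced cohorts. Implements variant quality control (exact
    Hardy-Weinberg test, missingness filters), functional classification of
    loss-of-function (LOF) variants at any-transcript and all-transcript
    stringency, comparison of sequencing against imputed genotypes (yield
    and allele-count concordance R-squared by minor allele frequency bin),
    per-gene LOF carrier counting with downsampling saturation curves and
    beta-binomial mixture extrapolation to larger cohorts, gene-collapsing
    burden association scans across binary and quantitative traits with
    Firth penalized logistic regression and single-variant, leave-one-out,
    stepwise and conditional decompositions, ClinVar-style filtering of
    medically actionable pathogenic variants, and penetrance estimation via
    contingency-table odds ratios, Fisher exact tests, Kaplan-Meier curves
    and Cox proportional hazards. A synthetic-cohort generator reproduces
    the statistical structure these analyses assume (heavy-tailed site
    frequency spectrum, Hardy-Weinberg genotypes, MAF-dependent imputation
    noise, planted burden effects and survival outcomes) so the full
    pipeline runs without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    vcfR,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
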