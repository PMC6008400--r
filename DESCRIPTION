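Package: bbdsomatic
Title: Somatic Mutation Filtering and Matched-Pair Burden Analysis for
    Benign Breast Disease Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a tumor/normal somatic variant
    post-processing pipeline for targeted gene-panel sequencing of benign
    breast disease (BBD) biopsies, and of the matched case-control
    statistics used to ask whether somatic mutations in BBD predict
    progression to invasive breast cancer.  Includes multi-caller ensemble
    merging by set algebra, a cascade of coverage, panel-of-normals,
    population-frequency and binomial log-likelihood somatic filters, an
    FFPE deamination (CG>TG, low-VAF) artifact screen, silent/non-silent
    effect annotation against a panel CDS model, paired burden tests with
    Benjamini-Hochberg correction, permutation gene-set enrichment, and a
    BBD/IBC progression overlap analysis.  A synthetic-cohort simulator
    with full ground truth stands in for the (non-deposited) patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    vcfR,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
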