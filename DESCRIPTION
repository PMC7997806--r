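Package: pressor
Title: Derived Intraoperative Pressor-Response Phenotypes and Mixed-Model
    Genetic Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving a rapid blood-pressure response phenotype
    (delta SBP/MAP/DBP around a phenylephrine bolus) from high-resolution
    perioperative vitals, applying a sequential inclusion/exclusion cascade
    with a full attrition table, comparing the derived phenotype across
    self-reported ancestry groups (Mann-Whitney and covariate-adjusted
    linear contrasts), scanning genotype dosages with a linear mixed model
    (genetic relationship matrix, principal components, REML null model,
    per-variant score test, genomic inflation factor), and testing
    enrichment of association signal in candidate genomic regions against
    size-matched random region sets. Includes a synthetic cohort generator
    with known ground truth (Balding-Nichols population structure,
    pharmacodynamic bolus-response traces, configurable exclusion flags)
    so the full pipeline is testable without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
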