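Package: lactospec
Title: Species-Specific Lactobacillus Protein Analysis for Cervicovaginal
    Metaproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for label-free quantitative metaproteomics of the
    cervicovaginal microbiota. Implements evidence-based post-identification
    inclusion filters for bacterial proteins (unique-peptide rules with an
    ANOVA/fragment-ion rescue path), a 16S-microarray-informed classifier
    that attributes shared Lactobacillus proteins to L. iners or
    L. crispatus by fold-change and median criteria against 16S-negative
    reference samples, cohort construction with vaginal pH categories and
    abundance strata, a pairwise Mann-Whitney comparison battery, and
    multivariable log-linear regression of protein abundance on microbiota
    group, pH category, and taxon abundance. A synthetic-data generator
    with planted effects supports parameter-recovery and calibration
    testing without access to raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
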