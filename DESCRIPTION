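Package: seedquant
Title: Quantitative Pipeline for Tau Seed-Amplification and Histology Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of tau seeding and early tau
    multimer pathology assays: extraction of RT-QuIC kinetic parameters
    (maximum ThT fluorescence, lag time against a baseline-derived 5-SD
    threshold, time to maximum fluorescence, maximum slope) with endpoint
    censoring at the assay cut-off; particle quantification of histology
    images by thresholding, connected components and micrometre-squared size
    windows separating diffuse from perikaryal lesions; GFAP burden;
    confidence-interval based stratification of samples into Double-Negative,
    Intermediate and Double-Positive pathology groups; scoring of FRET
    biosensor cell fields for the percentage of inclusion-bearing cells; and
    the group-comparison statistics layer (one-way ANOVA with Dunnett or
    Bonferroni post-hoc tests, two-way ANOVA with Dunnett comparisons against
    a control condition). Includes a fully seeded synthetic-data generator
    producing plate-reader curves, histology and FRET images with ground
    truth, and an end-to-end cohort pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    mvtnorm
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
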