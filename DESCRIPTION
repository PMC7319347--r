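Package: dsgxe
Title: Differential Susceptibility Analysis for Gene-by-Environment
    Interaction Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits covariate-adjusted moderated regressions for
    gene-by-environment interaction studies and runs the Roisman
    differential-susceptibility confirmation suite: Johnson-Neyman
    regions of significance, crossover point, proportion of interaction
    (PoI), proportion affected (PA), mean-split simple slopes, and a
    quadratic robustness check, with Benjamini-Hochberg false discovery
    rate control across models.  Includes SNP quality control
    (call rate, exact Hardy-Weinberg test, minor allele frequency),
    predicted tissue gene expression as a weighted dosage sum applied
    from a PrediXcan-style weight table, ancestry principal components,
    PCA-based socioeconomic composite construction with KMO and Bartlett
    diagnostics, behavioral phenotype scoring (ad-libitum buffet meal,
    Perceived Stress Scale, food go/no-go), and a seeded synthetic
    cohort generator that emulates the full data structure for testing
    and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
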