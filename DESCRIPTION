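Package: vdburden
Title: Case-Control SNP Association and Minor-Allele Burden Analysis for
    Vitamin D Pathway Variants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for candidate-gene case-control association
    studies of biallelic SNPs, built around a four-SNP vitamin D pathway panel
    (DHCR7, GC, CYP2R1, CYP24A1) and type 1 diabetes. Provides genotype table
    readers and count derivation, Hardy-Weinberg equilibrium goodness-of-fit
    tests, per-SNP logistic-regression association under five genetic
    inheritance models with AIC model selection and Bonferroni correction,
    a cumulative minor-allele burden score with a dichotomized odds-ratio
    test, case-control power and minimum-detectable-OR calculations, and a
    synthetic cohort simulator (Hardy-Weinberg genotypes, logistic disease
    model, covariates, assay-failure missingness) for validation by parameter
    recovery. Printed study count tables ship as fixtures so every result is
    recomputable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
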