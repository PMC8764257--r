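Package: clonalGS
Title: Pedigree- and Marker-Based Genetic Evaluation of Clonally
    Replicated Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genetic evaluation of clonally replicated tree trials with
    pedigree-based (ABLUP) and marker-based (GBLUP) individual-tree mixed
    models fitted by average-information REML, including separable
    AR1xAR1 spatial residuals, narrow-sense heritability, bivariate
    genetic correlations, cross-validated breeding-value accuracy and
    relative selection efficiency.  Ships readers for pedigree, SNP
    genotype (VCF or matrix) and phenotype/layout tables, a VanRaden
    genomic relationship matrix with the standard MAF/missingness
    filters and mean imputation, trait descriptive statistics including
    carbon isotope composition, and a synthetic-data generator
    (pedigree simulation, gene dropping, spatially structured clonal
    trials) with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
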