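Package: skimpute
Title: Skim-Sequencing Genotyping, Haplotype Imputation and Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genotyping-by-sequencing from low-coverage ("skim")
    long-read data. Implements genotype-likelihood calling from base qualities
    with strand-aware masking of CpG methylation artefacts, a coverage-binned
    minimum-allele-count caller, reference-panel construction with minor allele
    frequency filters, two Li-Stephens haplotype HMM imputation engines (a
    diploid genotype-likelihood engine and a read-aware engine that assigns
    reads to parental gametes by Gibbs sampling and imputes each gamete as a
    haploid), SNP-BLUP genomic estimated breeding values, and the evaluation
    metrics used to compare genotyping sources: Pearson correlations with
    confidence intervals, prediction bias, imputation accuracy, duplicate-run
    concordance and quartile re-ranking. A synthetic-data module simulates
    haplotype reference panels, diploid samples, SNP effects and noisy long
    reads so the whole pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
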