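Package: lohtarget
Title: Collateral-Lethality Target Discovery from Prevalent Loss-of-Function
    Alleles and Loss of Heterozygosity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for identifying cancer therapy targets whose wild-type
    allele is recurrently lost by loss of heterozygosity (LOH) while a
    loss-of-function (LoF) allele is prevalent in the population. Provides
    transcript-model-aware consequence annotation (premature stop, frameshift,
    canonical splice-site disruption), a staged population-genetics filter
    cascade with allele-frequency, heterozygosity, protein-position,
    expression, LOH and gene-family filters ending in a five-class LoF
    mechanism classification; CYP2D6 star-allele diplotype calling from
    QC-filtered variant calls with metabolizer phenotype prediction
    (UM/EM/IM/PM); viability normalization, logistic dose-response IC50
    fitting and two-stage differential-toxicity hit calling for paired
    cell-line drug screens; and seeded synthetic-data generators
    (Hardy-Weinberg genotype cohorts, transcript models, screening plates,
    organoid call sets) so the whole pipeline is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    minpack.lm,
    vcfR,
    optparse,
    Biostrings,
    rtracklayer,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
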