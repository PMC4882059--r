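Package: cd177conv
Title: Genotyping CD177/CD177P1 Gene Conversion from Read Dosage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers gene-conversion state at the human CD177 neutrophil
    antigen locus from amplicon deep-sequencing allele counts. Reads over
    CD177 exons 4-9 collapse the gene with its CD177P1 pseudogene, so
    variant-allele fractions at paralogous sequence variants are quantized
    in quarters of the four homologous copies; the package calls these
    quanta with exact binomial confidence intervals, classifies samples as
    reference-homozygous, ectopic-conversion heterozygous or CD177null,
    localizes conversion breakpoints, confirms copy structure by MLPA-style
    probe-ratio normalization, and tests Hardy-Weinberg structure,
    genotype-phenotype association and Mendelian transmission. Includes a
    synthetic locus and full study simulator with truth sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
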