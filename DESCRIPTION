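Package: darcsign
Title: Classifying DNA Repair Defects from ctDNA Whole-Exome Somatic Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns tumour/normal whole-exome small-variant calls and
    allele-specific copy-number segments from high tumour-fraction plasma
    cell-free DNA into a 224-dimensional somatic feature vector (96
    trinucleotide substitution channels, 83 indel channels, 45 copy-number
    segmentation features), trains one-vs-rest gradient-boosted tree
    classifiers for BRCA2, CDK12 and mismatch-repair deficiency phenotypes,
    derives F1-optimal decision thresholds, and explains classifications with
    additive (Shapley) feature attributions. Includes bespoke cell-free DNA
    somatic variant filters with a matched-leukocyte background error model,
    constrained signature refitting, homologous-recombination scar scores
    (HRD-LOH, LST, telomeric allelic imbalance), and a synthetic-cohort
    simulator emulating the phenotype classes so the full pipeline is testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    xgboost,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    vcfR,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
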