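Package: whitecoat
Title: Recessive Candidate-Gene Variant Discovery for Coat-Colour Dilution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discovering fully penetrant
    recessive coding variants from a sequenced affected/obligate-carrier pair
    and a genotyped validation cohort, built around the search for the
    white-coat dilution allele in fallow deer (MC1R c.143T>C, p.L48P).
    Provides a minimal VCF reader/writer, a strand-aware coding-effect
    annotator with codon arithmetic and capitalised-codon notation, the
    candidate filtering cascade (indel-proximity quality control, colour-gene
    subsetting, non-synonymous restriction, recessive trio filter, staged
    validation-panel refinement), an exact Fisher r-by-c association test by
    margin-constrained enumeration, carrier-frequency and concordance
    summaries, and a Hardy-Weinberg cohort simulator so that every stage is
    testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
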