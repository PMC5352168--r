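Package: thermode
Title: Differential Expression from Unreplicated Temperature-Contrast RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for differential-expression analysis of unreplicated,
    pooled-embryo RNA-seq designs contrasting two incubation temperatures
    across developmental stages in two species. Implements per-gene Fisher
    exact tests on a gene-versus-remaining-genes count contingency table
    with tiered Benjamini-Hochberg false-discovery control, four
    upper-quartile and housekeeping-gene normalization schemes, multinomial
    library subsampling for pseudo-replicated consensus calls, cross-stage
    and cross-species overlap and direction-concordance summaries, and a
    synthetic count generator with ground truth for power and FDR
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
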