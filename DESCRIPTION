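Package: gutseed
Title: Reverse-Ecology Screening of Probiotic Communities and Prebiotic Foods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reverse metabolic analysis of candidate probiotic gut
    bacteria. Parses genome-scale metabolic models (SBML or two-column edge
    lists) into directed compound graphs, detects seed sets (exogenously
    required metabolites) via strongly connected component condensation,
    computes pairwise reverse-ecology indices (biosynthetic support, metabolic
    complementarity, metabolic competition), partitions community nutrient
    requirements into core, strain-specific and shared compounds, performs
    hypergeometric pathway enrichment of seed compounds, matches seed
    metabolites into a food-composition table and ranks candidate prebiotic
    whole foods with a weighted category score, and extracts dictionary-driven
    sentence co-mentions from an annotated literature corpus. A synthetic-data
    module generates every pipeline input with planted ground truth so the full
    workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    stringi,
    readr,
    xml2,
    igraph,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
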