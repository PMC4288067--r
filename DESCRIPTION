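Package: conceptpaths
Title: Transitive Relationship Mining on Biomedical Concept Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hub-removal k-neighborhood distance labeling (kDLS) for large
    sparse biomedical concept graphs such as the UMLS Metathesaurus, with
    transitive distance and multi-path queries answered by label comparison.
    On top of the index it provides a semantic-type-weighted closeness
    measure aggregated over discovered paths, relationship and distance
    matrices between concept sets with threshold-based binarization and
    percentile-matched threshold transfer, fold-enrichment crossvalidation
    of ranked relation pairs against an external reference set, and
    deterministic layered layouts of shortest-path networks. Readers are
    included for UMLS RRF subsets and a generic TSV dialect, together with a
    power-law synthetic graph generator so every stage is testable without
    licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
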