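Package: generifsel
Title: GeneRIF Sentence Selection from MEDLINE Citations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies sentences in biomedical citations that describe novel
    gene function (GeneRIF candidates). Provides a citation/sentence data
    model with readers for PubMed-style XML and a line-oriented fixture
    dialect, rule-based sentence segmentation, a human gene-name dictionary
    with variant generation, longest-first mention matching, Schwartz-Hearst
    abbreviation resolution and two normalization strategies (officialness
    ranking and profile-based disambiguation), discourse labeling of abstract
    sentences distilled from structured abstracts (a boosted-tree one-vs-rest
    ensemble and a linear-chain sequence labeler), per-sentence feature
    extraction (position, discourse, gene mentions, Gene Ontology term
    density, bag-of-words), standard classifiers for GeneRIF sentence
    selection with top-3 ranking, automatable citation-filtering rules, and a
    seeded synthetic-corpus generator for end-to-end testing.
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
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    xml2,
    e1071,
    rpart,
    xgboost,
    Matrix,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
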