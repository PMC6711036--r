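Package: bowelwatch
Title: Mining Bowel-Disease Conversations from Tweet Archives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for characterizing the bowel-disease
    (inflammatory bowel disease and irritable bowel syndrome) community in
    archived tweet collections. Provides tweet normalization (hashtag
    splitting, repeat squeezing, spelling correction by normalized
    Levenshtein similarity, abbreviation expansion, n-gram construction),
    rule-cascade user profiling (gender, organization/patient/expert,
    gazetteer geolocation with time-zone disambiguation), inverted
    longest-match lexicon entity recognition over five semantic categories,
    a valence-lexicon sentiment scorer, interaction and term co-occurrence
    network analysis, and the summary tables used in infodemiology reports.
    A seeded synthetic-corpus generator with planted ground truth makes every
    stage testable without live data collection.
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
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
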