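Package: misinfotrack
Title: Active-Learning Surveillance of Vaccine Misinformation on Social Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for profiling the spread of vaccine
    misinformation in Twitter-like corpora. Provides readers and validators
    for tweet and user tables, a synthetic corpus generator with
    class-conditional vocabulary and account characteristics, weak labeling
    via keyword include/exclude queries, a pool-based active-learning
    classifier built on a linear support vector machine with
    uncertainty-batch selection, gazetteer-based location normalization,
    weekly time-series aggregation with min-max normalization, and
    demographic, engagement and bot-score comparisons between
    misinformation-spreading and fact-sharing accounts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
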