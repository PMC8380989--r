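Package: ginilag
Title: Gini Correlation Analysis of Developmental Lags Between Gene
    Expression and Cell Wall Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for relating transcript abundance to phenotypic traits
    measured along an ordered developmental series, built around the Gini
    correlation coefficient with permutation p-values and false discovery
    rate q-values. Implements concurrent, delta (change-score), and
    cumulative lag models pairing gene expression at one developmental
    position with cell wall traits at the same or a later position;
    expected/unexpected sign classification with precision-recall model
    scoring; significant-correlation network construction with SIF and
    GraphML export; efficiency-adjusted delta-Cq conversion of qPCR data;
    one-way ANOVA with Tukey-Kramer range tests and compact letter
    displays; and a synthetic data generator that emulates the assumed
    statistical structure (mid-series expression pulse, lagged cumulative
    deposition, concurrent tracking, digestibility decline) for testing
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
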