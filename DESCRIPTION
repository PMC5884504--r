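Package: countylang
Title: County-Level Language Epidemiology from Topic-Scored Corpora
Version: 0.1.0
Authors@R:
    person("Maintainer", "countylang", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for relating aggregate social-media language to
    county-level health outcomes. Scores geographic units on
    lexicon-defined topics from raw token counts, predicts an outcome
    rate from those scores with and without socio-demographic controls
    (feature screening, PCA, ridge regression under 10-fold
    cross-validation), ranks topics differentially associated with the
    outcome under Benjamini-Hochberg false-discovery control, and
    screens every topic as a mediator of the socioeconomic
    status-outcome relationship using the Sobel test. Includes a
    synthetic county-corpus generator with planted effects so the whole
    pipeline is testable without access to restricted survey or
    social-media data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
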