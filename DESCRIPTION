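Package: lasamatch
Title: Spatial-Coding Orthographic Similarity Screening for Look-Alike Drug Names
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores orthographic similarity between pairs of drug proprietary
    names with a spatial-coding match value: letter positions are encoded as a
    monotonically descending activity series, signal-weight differences between
    a stored word and an input string are superposed as Gaussian difference
    functions, and the peak of the superposition, normalized by the
    comparison-letter count, yields a match value in [0, 1]. Match values are
    banded into low/medium/high confusion-risk classes used in look-alike
    sound-alike (LASA) medication-safety screening. Includes pair-table and
    formulary I/O, a packaged 100-pair Iranian registry (GOTR) dataset, a
    convention-sweep reproduction report, a seeded synthetic name-pair
    generator for property testing, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
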