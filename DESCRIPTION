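Package: bfnull
Title: Default Bayes Factors for Null Results in Contingency Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the evidence that a nonsignificant comparison of
    proportions actually provides for the null hypothesis. Implements the
    default Bayes factor (BF01) for m x k contingency tables under
    independent-multinomial sampling with symmetric Dirichlet priors, the
    Pearson chi-square test with and without Yates' continuity correction,
    Jeffreys-style evidence categories, a corpus pipeline relating p-values
    and sample sizes to the strength of evidence for the null across many
    studies, and a generator of synthetic null-result corpora that emulates
    samples of published two-arm trials screened for nonsignificance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
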