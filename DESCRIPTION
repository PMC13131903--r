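Package: tractconcord
Title: Cross-Pipeline Concordance of Tractometry Sex Differences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical machinery for asking whether two tractography
    pipelines applied to the same cohort lead to the same conclusions about
    sex differences in white-matter tracts. Takes per-subject tract-feature
    tables from two pipelines, runs pooled two-sample t-tests with Bonferroni
    control and Cohen's d effect sizes for every tract-feature pair, classifies
    each pair of results into a six-category significance-and-direction
    agreement taxonomy with strict and soft composite levels, and compares
    pipeline sensitivity via a stratified, subject-paired percentile bootstrap
    of the difference in effect-size magnitude. Includes a synthetic
    two-pipeline cohort generator with exactly controlled effect sizes and
    between-pipeline correlation so the whole analysis is testable without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
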