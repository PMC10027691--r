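Package: wmconn
Title: Connectivity-Pattern Decoding of Auditory Working Memory Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate pattern analysis of working-memory content from
    functional-connectivity patterns between cortical regions of interest.
    Builds class-specific Pearson correlation matrices across subROI pairs of
    2-4-region networks from residualized BOLD time series, decodes the
    maintained stimulus class with a linear support vector machine under
    leave-one-run-out cross-validation, and assesses group-level significance
    with a family-wise maximum-statistic permutation test. Includes a
    moving-ripple stimulus synthesizer, an adaptive-staircase simulator, a
    retro-cue trial scheduler, and a synthetic multi-subject BOLD generator in
    which memory content is carried by class-dependent inter-region coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
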