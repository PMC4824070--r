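Package: termeff
Title: Termination Efficiency of Intrinsic Terminators Under
    Transcription-Translation Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies in vivo termination efficiency (TE) of
    Rho-independent (intrinsic) terminators from dual-fluorescence
    plate-reader time series, with growth-rate and fluorophore-maturation
    corrections; models the TE-distance relation as stochastic coupling
    between the pioneer ribosome and RNA polymerase via a Poisson
    ribosome-position model TE(d) = TE0 * (1 - CDF(alpha, d + c)), with
    exhaustive-grid least-squares fitting and bootstrap uncertainty; and
    provides a mechanistic Gillespie simulator of coupled
    transcription-translation elongation that grounds the Poisson
    approximation. Includes synthetic-data generators for reporter growth
    curves and TE-distance tables, and a spacer-sequence designer for
    forward engineering of TE by terminator position.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
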