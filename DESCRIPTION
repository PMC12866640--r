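Package: fracprop
Title: Compositional Correction and Differential Proportion Testing for
    Fractionated RNA-Seq
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the original proportions of sequenced RNA fractions
    (light/heavy polysomes, nuclear/cytoplasmic, and similar designs),
    including the unrecoverable "lost" fraction, from raw count matrices of
    a whole-lysate library and its fraction libraries.  A non-negative
    least squares regression of total counts on fraction counts yields
    per-fraction normalization coefficients, from which global fraction
    weights and depth-corrected per-transcript proportions are derived.
    Differential proportion testing between two conditions is provided via
    a binomial GLM likelihood-ratio test, an empirical-logit test, and a
    beta-binomial Wald test, with Benjamini-Hochberg correction.  A
    ground-truth simulator (heavy-tailed abundances, Dirichlet-multinomial
    allocation, binomial library thinning) supports validation without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
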