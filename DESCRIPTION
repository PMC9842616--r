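Package: riskconform
Title: Simulating and Analysing Social Conformity in Risky Moral and
    Monetary Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how social norms reshape risk preferences
    in a parametric gamble task adapted from the Asian Disease Paradigm.
    Provides a generative simulator of participants with Prospect-Theory
    preferences (curvature, loss aversion, choice temperature) who shift
    toward experimentally constructed risk-averse or risk-seeking group
    norms, and the matching analysis chain: per-participant Prospect-Theory
    maximum-likelihood fits, random-intercept mixed-effects logit models
    with adaptive Gauss-Hermite quadrature, marginal gamble probabilities
    and multiplicity-adjusted contrasts, conformity-influence curves and
    their persistence at a three-day retest, a binary-entropy analysis of
    choice consistency, awareness-conformity correlation, and the quality
    control exclusion rules of the two-session design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    lme4,
    MASS,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
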