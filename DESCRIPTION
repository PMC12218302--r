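Package: mediabo
Title: Bayesian-Optimization-Based Iterative Experimental Design for
    Cell Culture Media Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for closed-loop, Bayesian-optimization-driven design of
    cell culture media experiments over mixed continuous, discrete and
    categorical design factors, with optional linear equality constraints
    such as blend ratios summing to one. Provides Gaussian-process
    surrogates with a Matern kernel over continuous factors combined with a
    categorical overlap kernel, fixed replicate-derived process noise,
    upper-confidence-bound and Thompson-sampling acquisition, EXP3
    multi-armed bandit selection of categorical arms, constant-liar
    batching, transfer learning onto extended design spaces, synthetic
    benchmark landscapes with certified optima, a design-of-experiments
    budget calculator, and a campaign ledger with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
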