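Package: thresholdPGG
Title: Aspiration Dynamics of the Multi-Player Threshold Public Goods Game
    with Payoff Redistribution
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact and approximate analysis of the average abundance of
    cooperators in a finite well-mixed population playing a multi-player
    threshold public goods game with a redistribution (second-order payment)
    mechanism, evolving under aspiration-driven stochastic dynamics with
    mutation. Provides hypergeometric expected payoffs, the birth-death
    transition probabilities, the detailed-balance stationary distribution
    computed stably in log space, the exact average abundance function,
    closed-form weak-selection and strong-selection approximations with
    validity diagnostics, the critical multiplication factor and the
    abundance-maximising threshold, a Monte-Carlo simulator used as an
    independent cross-check, and a config-driven parameter sweep runner with
    a thin command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
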