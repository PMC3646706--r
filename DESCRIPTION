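Package: coalmig
Title: Gene Tree Simulation Under the Multispecies Coalescent with
    Time-Dependent Migration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates gene genealogies evolving inside a species tree
    under the structured (multispecies) coalescent when both effective
    population sizes and migration rates change continuously over time.
    Demographic and migration histories are piecewise-linear functions of
    time, for which event waiting times are drawn exactly by
    inverse-transform sampling of analytically integrated hazards. The
    package includes a gradual-separation scenario generator for species
    trees, Jukes-Cantor sequence simulation along the resulting gene
    trees with the usual population-genetic summaries, and two
    independent validation oracles (an Euler small-step simulator and a
    continuous-time Markov chain matrix-exponential closed form for the
    constant-rate two-population case).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Matrix,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
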