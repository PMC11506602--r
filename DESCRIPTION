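Package: salrmix
Title: Lattice Monte Carlo for Binary Mixtures with Competing Short-Range
    Attraction and Long-Range Repulsion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pattern formation in a two-component triangular-lattice gas of
    membrane inclusions interacting through short-range attraction and weak
    long-range repulsion, with cross interactions of the opposite sign.
    Provides exact ground-state phase diagrams from a periodic pattern
    library backed by a brute-force enumeration oracle, grand-canonical
    Metropolis Monte Carlo with parallel tempering along chemical-potential
    ladders, canonical-ensemble annealing at fixed composition, and
    structural observables (lattice structure factors, cluster statistics,
    periodicity detection) together with compressibility and specific-heat
    fluctuation estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
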