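Package: ipdnet
Title: Divide-and-Conquer Iterated Prisoner's Dilemma Tournaments on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates divide-and-conquer iterated Prisoner's Dilemma
    tournaments on social networks. Fourteen classic strategies (from
    unconditional cooperation through tit-for-tat variants to
    zero-determinant extortion) play independent iterated games on every
    edge of a Watts-Strogatz or Barabasi-Albert graph; node fitness is the
    accumulated or degree-averaged epoch payoff, and strategies spread by
    best-takes-over imitation in the closed neighbourhood. The package also
    provides exact long-run expected payoffs for strategy pairs via the
    Press-Dyson determinant formula, deterministic cycle detection, and
    finite-state Markov chain analysis, a round-robin scoreboard with the
    weak/strong designation, degree-ranked strategy seeding, and seeded
    alpha-sweep experiment grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
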