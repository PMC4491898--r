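Package: paretodp
Title: Pareto-Front Multi-Objective Dynamic Programming on Evaluation Algebras
Version: 0.1.0
Authors@R:
    person("paretodp", "maintainers", email = "paretodp@example.org",
           role = c("aut", "cre"))
Description: A small algebraic dynamic-programming (ADP) engine with a
    generic Pareto product on evaluation algebras. Provides two-dimensional
    Pareto-set mathematics (domination, five Pareto-front operators, a
    linear-time Pareto merge, harmonic-law front-size expectation), tree
    grammars with tabulated evaluation, algebra products (lexicographic,
    weighted-additive and Pareto, the latter with standard, sorted and
    Pareto-eager evaluation strategies), and two worked applications from
    RNA sequence analysis: single-sequence secondary-structure folding
    under a free-energy versus expected-accuracy bi-objective, and the
    Sankoff problem of joint pairwise alignment and consensus folding
    under similarity versus base-pairing objectives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
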