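Package: blackwellpid
Title: Partial Information Decomposition via the Blackwell Order
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes partial information decompositions (PID) of the
    information that a set of discrete source variables carries about a
    target variable. Implements order-based redundancy and union
    information built on the Blackwell order (channel degradation),
    including the polytope vertex-enumeration scheme for redundancy, the
    convex marginal-matching program for union information, derived
    unique, synergy and excluded information, decision-theoretic order
    oracles (value of information, utility-game falsification), and the
    classical baseline measures (minimum mutual information,
    deterministic-function redundancy, conditional-independence
    redundancy, Gacs-Korner common information). Ships generators for the
    standard logic-gate benchmark distributions and a command-line tool.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
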