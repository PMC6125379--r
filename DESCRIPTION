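Package: prejsim
Title: Evolution of Prejudicial Groups Under Indirect Reciprocity
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of the co-evolution of cooperation and
    out-group prejudice under indirect reciprocity. Agents play one-shot
    donation games decided by social comparison of reputations under a
    generalized standing norm, hold a prejudice level that discounts the
    universal reputation of out-group members, and form "prejudicial groups"
    of agents sharing an immutable trait and a common prejudice level.
    Natural selection follows an island model: fitness-proportional copying
    of strategies, mostly within the group, with per-element mutation.
    Includes preset experiment scenarios (strategy co-evolution, fixed
    interaction/learning grids, trait-count sweeps, imbalanced
    sub-populations), a fast compiled event loop, a pure-R reference engine
    that reproduces the compiled engine bit-for-bit, and per-generation
    metric tables with multi-run aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
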