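Package: mromgla
Title: Interactive-Activation Word Recognition, Global Lexical Activity,
    and GLA-Linked Region Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates visual word recognition with an interactive-activation
    network over a lexicon and the multiple read-out model's (MROM) three
    lexical-decision criteria (unit identification, global-activity fast
    guess, temporal deadline).  Computes global lexical activity (GLA) as the
    mean summed positive word-unit activation over the first processing
    cycles, together with the orthographic statistics it tracks (Coltheart's
    N, neighborhood frequencies, bigram counts).  Provides the full stimulus
    construction chain (nonword pool generation by letter substitution,
    constrained selection of word and nonword sets with normal z-GLA
    distributions, tertile GLA leveling, descriptor tables and
    GLA-structure correlations), balanced two-by-three repeated-measures
    ANOVA with polynomial trend contrasts and simple-effect decomposition
    for per-region signal-change tables, and seeded synthetic generators
    for lexicons and region signals so every stage is testable without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
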