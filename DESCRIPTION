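Package: chemtoxgraph
Title: Chemical Substructure Similarity Networks with Toxicity Overlap and
    Microbial Enzyme Dominance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a queryable property graph linking food, drug and
    endogenous compounds through chemical substructure similarity,
    side-effect-based toxicity similarity and microbial enzyme annotations.
    Compounds carry 881-bit PubChem-style substructure fingerprints compared
    with the Tanimoto coefficient; the similarity network is filtered,
    clustered with Walktrap random-walk community detection, and edges are
    flagged by per-community Z-score. Drug toxicity similarity follows the
    Campillos approach: side-effect concept rarity weighting combined with
    Gerstein-Sonnhammer-Chothia tree weights that down-weight redundant
    concepts. A Simpson-index dominance score summarises how taxonomically
    concentrated each microbial enzyme is. Validation utilities compare the
    network against degree-free randomizations, regress toxicity on
    structure, and train a calibrated margin classifier for the probability
    that two compounds share an enzyme. Seeded synthetic-fixture generators
    emulate every input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    e1071,
    ape,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
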