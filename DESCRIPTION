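Package: openlbd
Title: Open Literature-Based Discovery with Supervised Linking-Concept Selection
Version: 0.1.0
Authors@R:
    person("Ira", "Lachmann", email = "ira.lachmann@example.org", role = c("aut", "cre"))
Description: Tools for open literature-based discovery (LBD) over
    MEDLINE-style bibliographic records using the ABC co-occurrence model.
    Starting from a concept C, candidate linking concepts B are collected
    from MeSH co-occurrence, represented by two mutual-information features
    and five sentence-level textual features, and filtered with a linear
    margin classifier before target concepts A are discovered, ranked by
    useful linking-term counts under two textual-evidence rules, and
    evaluated with the percentage-of-useful-LTC metric. Includes a MEDLINE
    flat-file parser/writer, sentence segmentation with abbreviation-aware
    concept mention detection, semantic-type filtering, and a seeded
    synthetic-corpus generator with planted ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
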