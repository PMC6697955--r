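Package: thbpmap
Title: Map Anatomical Mentions in Clinical Text to a Body-Part Ontology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps anatomical related entities found in clinical discharge
    summaries to nodes of a hierarchical, position-based ontology of human
    body parts (the Tree of Human Body Parts, THBP). Combines a stemmed
    string-matching baseline, a named-entity-normalization stage
    (stopword removal, singularization, positional-word splitting,
    abbreviation expansion via dictionary and coreference chains), and a
    knowledge-base fallback that scores candidate body parts found in an
    encyclopedia explanation text by occurrence distance and frequency.
    Ships a hand-authored THBP ontology, resource dictionaries, a fixture
    knowledge base, a synthetic-corpus generator, and mention-level
    precision/recall/F1 evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
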