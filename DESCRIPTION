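Package: rhythmhic
Title: Temporally Resolved 3D-Genome Analysis Across the Circadian Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multi-timepoint Hi-C and promoter capture Hi-C data
    sampled across the circadian cycle. Detects A/B chromatin compartments and
    oscillatory chromatin compartments (OCCs) from PC1 eigenvectors, calls
    topologically associating domains (TADs) from insulation scores, classifies
    circadian genes from replicated expression tables, relates circadian genes
    to TADs and OCCs, classifies promoter contacts as dynamic or stable with a
    negative-binomial likelihood-ratio test, runs matched-permutation feature
    enrichment at promoter-interacting regions, builds promoter-promoter
    interaction networks, and ships a seeded synthetic-data generator that
    plants every structure the pipeline measures so the full analysis is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    jsonlite,
    yaml,
    IRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
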