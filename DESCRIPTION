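Package: reefzoner
Title: Rule-Based Geomorphic Zonation of Coral Reefs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An executable implementation of the Reef Cover geomorphic
    classification for shallow tropical coral reefs. From co-registered grids of
    bathymetry, significant wave height and sub-surface brightness it derives
    slope, exposure and texture attributes, assigns the 17 internal reef classes
    (plus Deep Water and Land context classes) with a transparent decision-tree
    ruleset, checks and repairs the map against relational adjacency and
    enclosure rules, and summarises areal extents with crosswalks to the two
    published case-study legends. A seeded synthetic reef-archetype generator
    (atoll, fringing, platform, barrier) produces attribute stacks with ground
    truth labels so the whole pipeline is testable without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
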