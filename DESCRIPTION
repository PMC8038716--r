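Package: mutualaid
Title: Mutual-Assistance Capability Mapping and Multi-Agent Earthquake
    Evacuation Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Support tool for drafting community disaster management plans.
    Evaluates neighbourhood mutual-assistance (rescue) capability from a
    demographic roster and building locations, using age- and gender-specific
    expected rescue values with a distance-decay weight and impassable-barrier
    exclusion, and an unweighted per-group surplus/shortage accounting.
    Couples the evaluation to a one-second-step multi-agent evacuation
    simulator on a road network under precomputed earthquake hazard timelines
    (building collapse, rubble road blockage, wind-biased cellular-automaton
    fire spread), with batch summaries, map-form outputs, a synthetic town
    generator for self-contained experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
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
RoxygenNote: 7.3.3
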