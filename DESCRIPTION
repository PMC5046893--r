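Package: trophicscape
Title: Trait-Based Ecosystem Simulation of Habitat Loss and Fragmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, cohort-based, spatially explicit multi-trophic
    ecosystem simulator for factorial habitat loss and fragmentation
    experiments. Heterotrophs are modelled as cohorts defined by functional
    traits (trophic group, thermoregulation, reproductive strategy, body
    masses) and autotrophs as per-cell leaf and structural biomass pools on a
    bounded grid. A scenario engine crosses impact extent, intensity, and
    spatial configuration (random versus contiguous) of monthly plant-biomass
    removal, and response metrics quantify trophic skew of the biomass
    pyramid, top-down mitigation of autotroph loss, and patch occupancy by
    trait class, together with the subset regressions and paired comparisons
    used to read the factorial design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
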