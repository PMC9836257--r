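Package: limeval
Title: Lime Versus Fertilizer Economics for Acid-Soil Remediation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to evaluate agricultural lime against nitrogen fertilizer
    as remedies for acid-soil yield losses in wheat and barley. Computes lime
    requirements from soil chemistry (cation exchange capacity and a
    pH-to-base-saturation buffer model), fits polynomial fixed-effects yield
    response surfaces to sub-kebele panel data with nested-ANOVA order
    selection, derives spatially explicit delivered lime prices from a
    least-cost travel-time model over a friction surface, and compares
    five-year present-value costs of the two interventions ("x cost of
    lime"). A synthetic-data generator emulates the panel, landscape, and
    crusher inputs with known planted responses so that every stage is
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
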