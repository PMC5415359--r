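Package: k2pflex
Title: Mechanogating Analysis of K2P Channel Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for mechanosensitive two-pore domain (K2P)
    potassium channels. Quantifies the down/up conformational transition
    (Kabsch RMSD to reference structures, fenestration/zipper/expansion
    gating distances, state classification and event-order detection),
    membrane geometry (cross-sectional area profiles, bilayer thickness,
    area per lipid), lateral pressure profiles from a z-binned
    Hardy/Irving-Kirkwood local stress tensor, and occupancy analyses
    (selectivity-filter ion sites S0-S4, pore hydration and dewetting,
    lipid-protein contacts). Includes synthetic-data generators with
    recorded ground truth so every stage is testable without MD runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
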