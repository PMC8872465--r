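Package: sirscan
Title: Subregion Thermodynamic Scanning for siRNA Off-Target Analysis
Version: 0.1.0
Authors@R:
    person("Panel", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes nearest-neighbor melting temperatures (Tm) for every
    subregion of an siRNA guide strand, correlates subregion thermodynamic
    stability with relative luciferase activities from complete-match (CM,
    on-target) and seed-match (SM, off-target) reporter assays, and localizes
    the subregions most responsible for the seed-dependent off-target effect
    by repeated random subsampling with train/validation correlation
    comparison. Ships a seeded synthetic-data generator that emulates a panel
    of rule-compliant siRNAs so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
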