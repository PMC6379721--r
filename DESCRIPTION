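Package: origametry
Title: Structural Analysis of Coarse-Grained DNA Origami Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the structure of DNA origami from
    coarse-grained nucleotide-level configurations and trajectories.
    Reads and writes oxDNA-style topology and configuration files, imports
    caDNAno designs and builds relaxed initial configurations, measures
    Holliday-junction twist (phi) and splay (theta) angles with windowed
    umbrella sampling combined by WHAM into free-energy landscapes,
    quantifies the weave and corrugation patterns of origami sheets,
    computes mean structures, Kabsch superpositions and RMSDs, and detects
    helix-path helicity in 3D bundles. A seeded synthetic-trajectory
    generator produces duplexes, stacked-junction ensembles, weave tiles
    and square-lattice bundles with recorded ground truth, so every
    analysis can be validated at desk scale without a molecular-dynamics
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
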