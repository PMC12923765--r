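Package: pi3kdyn
Title: Trajectory Analytics for PI3K-Alpha Variant Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics ensembles of PI3K-alpha
    variants and for same-gene double-mutation catalogs. Provides multi-model
    PDB trajectory input, interface salt-bridge ("latch") distance series and
    occupancy statistics, buried interface areas via Shrake-Rupley quadrature,
    two-dimensional potentials of mean force over distance reaction
    coordinates, Kabsch superposition with RMSD/RMSF profiles and ensemble
    clustering, dynamic cross-correlation networks with bounded-suboptimal
    allosteric path enumeration, membrane leaflet assignment with anchor-depth
    and PIP2-protrusion metrics and radial distribution functions, cryptic
    pocket screening rules, and co-occurrence/mutual-exclusivity statistics
    for somatic double mutations with driver-tier classification. Synthetic
    generators reproduce the statistical structure each stage assumes, so the
    whole pipeline is testable without external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
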