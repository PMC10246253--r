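Package: oligoscape
Title: Quaternary Structural Proteomes, Membrane Compartmentalization and
    Spatial Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Determines the best quaternary structural representation of
    protein complexes from gene stoichiometries and a catalog of
    experimental and predicted structure files; enumerates pseudo-structures
    (gene-per-entity assignments recreating a structure's chain
    stoichiometry), performs structure-guided reannotation of oligomeric
    states, and matches multisets of structures to complex targets.
    Assigns every residue of a proteome to one of nineteen subcellular
    compartments by fitting membrane leaflet planes to membrane-crossing
    residues parsed from UniProt topology, DeepTMHMM predictions and OPM
    output, with viability checks on plane angle, slab thickness and
    cross-sectional area.  Overlays sequence features, laboratory-acquired
    mutations and allele occurrence in 3D (proximity, Grantham severity,
    geometric interfaces, disulfides), and computes the convex-hull volume
    and membrane-footprint allocation of a model-predicted proteome.
    Includes deterministic synthetic-data generators so the full pipeline
    is testable without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
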