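Package: trajnet
Title: Comparative Trajectory Metrics and Dynamic Residue Networks for
    Protein Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares wild-type and missense-variant protein molecular
    dynamics trajectories. Provides multi-model PDB trajectory input and
    output, Kabsch superposition, per-frame RMSD and radius of gyration,
    per-residue RMSF, kernel density estimates of conformational sampling,
    dynamic cross-correlation matrices of alpha-carbon motion, and dynamic
    residue networks built from beta-carbon contact graphs (average
    shortest path L and betweenness centrality BC), with WT-minus-variant
    delta profiles and two-standard-deviation residue selection. Includes
    a seeded generator of protein-like synthetic trajectories with
    controllable fluctuation amplitudes, correlated group motions,
    rigid-body drift and two-state switching, and utilities for merging
    independently predicted binding-site residue sets into a consensus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
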