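Package: aptanet
Title: Correlation-Network and Interaction Analysis of Riboswitch Aptamer Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis of nucleic-acid--ligand trajectory
    ensembles, built around the 2'-deoxyguanosine riboswitch aptamer:
    superposition-based RMSD/RMSF per substructure, Altona-Sundaralingam
    pseudorotation analysis of the ligand furanose ring, geometric
    hydrogen-bond and Leontis-Westhof base-pair/stacking occupancy, and a
    correlation-network communication analysis (dynamic cross-correlation
    matrices, contact-filtered -log|C| weighted graphs, Yen's k-shortest
    suboptimal paths, node degeneracy and square-inner-product profile
    comparison). Includes synthetic-trajectory generators with known
    statistical ground truth so every stage is testable without molecular
    dynamics output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
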