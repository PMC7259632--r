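Package: epiturn
Title: Turn-Geometry and Interaction-Fingerprint Profiling of Amyloid Assemblies
Version: 0.1.0
Authors@R:
    person("Epiturn", "Developers", email = "epiturn@example.org", role = c("aut", "cre"))
Description: Structural analysis toolkit for deciding whether an amyloid-beta
    aggregate presents a conformation-specific antibody epitope. Reads single-
    and multi-model PDB files into a uniform structure/trajectory data model;
    computes epitope turn spans (Calpha-Calpha distances), Kabsch superposition,
    LRMSD and RMSF profiles, and Shrake-Rupley solvent-accessible surface areas;
    detects six classes of non-covalent interactions across an antibody-antigen
    interface with configurable distance cutoffs and labels salt bridges;
    aggregates per-frame fingerprints into contact occupancies over trajectories;
    and applies a composite positive/negative epitope-accessibility
    classification (sharp turn, solvent-exposed key lysine not sequestered in a
    salt bridge, uncrowded turn). Includes a deterministic seeded generator of
    synthetic peptides, interfaces, trajectories and multimeric stacks for
    testing, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
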