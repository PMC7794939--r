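Package: pharmflow
Title: Receptor-Based Pharmacophore Screening and Docking Pose Consensus Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structure-based virtual screening of small-molecule
    libraries against a protein binding site. Builds receptor-based pharmacophore
    models (typed feature spheres with mandatory/optional logic and excluded
    volumes) from a protein-ligand complex, screens multi-conformer libraries by
    rigid feature alignment, filters docking poses by explicit protein-ligand
    interaction geometry (hydrogen bonds, water bridges, hydrophobic contacts,
    pi-stacking), clusters poses across docking methods by complete-linkage on
    symmetry-aware in-place RMSD, and applies molecular-dynamics trajectory
    filters based on hydrogen-bond occupancy and ligand drift. Includes a
    deterministic synthetic-fixture generator (toy pockets, libraries with
    planted pharmacophore matches, pose ensembles with prescribed RMSD
    structure, trajectories with planted interaction occupancy) so the whole
    cascade is testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
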