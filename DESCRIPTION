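Package: kemlead
Title: Lead-Structure Prediction with the Counterpoise-Corrected Kernel
    Energy Method
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fragment-based estimation of protein-ligand interaction
    energies for docking pose adjudication and ligand ranking.  A
    protein-ligand complex is partitioned into kernels (single residues
    plus the ligand), severed bonds are capped with hydrogens, and total
    and pairwise interaction energies are reassembled from single- and
    double-kernel energies with counterpoise/raw averaging (KEM-CP).
    Includes a classical point-charge plus Lennard-Jones backend for
    exact desk-scale validation, Gaussian counterpoise input writing and
    log parsing, heavy-atom in-place RMSD pose classification, best-pose
    adjudication against a crystal-geometry RMSD cutoff, and rank
    comparison of interaction energies and docking fitness scores
    against experimental IC50 values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
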