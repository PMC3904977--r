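Package: protifr
Title: Protein-Protein Interface Residue Prediction from Structural Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts interface-forming residues (IFR) of protein complexes
    from structure-derived physicochemical descriptors. Parses PDB-format
    structures, computes per-residue solvent accessibility by numerical
    rolling-probe sampling, labels interface-forming versus free-surface
    residues by the accessibility change upon complexation, derives a suite
    of per-residue descriptors (contact energies, cross-link and
    cross-presence order, local density and sponge, hydrophobicity, screened
    electrostatic potential, backbone and side-chain dihedrals) together
    with their weighted neighbor averages, and trains amino-acid-type
    specific linear discriminant classifiers on decorrelated principal
    component scores. Includes a full ROC/MCC cross-validation harness,
    dataset filtering utilities, and seed-deterministic synthetic fixture
    generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
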