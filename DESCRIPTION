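Package: mfccr
Title: Per-Residue Protein-Ligand Interaction Energies by Molecular
    Fractionation with Conjugate Caps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fragment-based decomposition of protein-ligand binding energy
    into per-residue contributions using the molecular fractionation with
    conjugate caps (MFCC) scheme.  The receptor is cleaved at its peptide
    bonds, each residue is capped by its flanking residues with link
    hydrogens saturating the cut bonds, and the ligand-residue interaction
    energy is obtained as the four-term MFCC energy difference.  The package
    provides a classical dielectric-screened Coulomb plus Lennard-Jones
    backend, input-deck writing and log parsing for an external quantum
    chemistry engine, an incremental binding-pocket-radius convergence
    analysis with residue ranking and ligand-region energy aggregation, and
    a deterministic synthetic complex generator with a brute-force energy
    oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
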