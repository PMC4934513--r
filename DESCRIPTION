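Package: motifdock
Title: Template-Based Ligand Transplantation by Binding-Site Motif Congruence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Soft docking of small-molecule ligands by template transfer: the
    ligand-contact motif (an ordered set of protein atoms with pairwise
    distances and pairwise electrostatic-potential differences) is extracted
    from a known holoenzyme, spatially and electrostatically congruent motifs
    are searched in a target structure over a precompiled motif database, and
    the ligand is transplanted rigidly by superposing the congruent anchor
    atoms in a canonical three-point coordinate frame. Includes PDB input and
    output, an OpenDX scalar-grid reader with trilinear interpolation, a
    screened-Coulomb potential surrogate, contact and clash reports, PyMOL
    script output, synthetic fixture generators with known ground truth, and a
    command-line interface.
License: MIT
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
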