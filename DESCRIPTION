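Package: clamshell
Title: Rigid-Body Domain Motion Analysis for Two-Lobe Protein Structures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative conformational analysis of hinged ("clam-shell")
    two-lobe protein structures such as the catalytic domains of
    angiotensin-1-converting enzyme (ACE) and its homologue ACE2.
    Superposes open and closed conformations on an anchor subdomain,
    profiles per-residue C-alpha displacements, summarises the motion of
    named mobile regions, detects hinge residues, decomposes the opening
    motion into a screw axis (rotation angle, axis direction, axial
    translation), measures the displacement of active-site metals, and
    computes pairwise RMSD matrices across conformer sets.  Includes
    distance-based detectors for polar, hydrophobic, metal-coordination
    and water-bridged contacts to fingerprint peptide-receptor
    interfaces, and a synthetic clam-shell generator with analytic ground
    truth for end-to-end validation without any structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
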