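Package: pepscreen
Title: In Silico Screening of Protein-Derived Inhibitory Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for discovering candidate inhibitory
    peptides derived from a parent protein sequence: exhaustive subpeptide
    library enumeration with absolute coordinate mapping, pluggable
    sequence-based interaction scoring with reference-threshold filtering,
    docking-pose ensemble post-processing (pairwise RMSD, k-medoids
    clustering, occupancy and energy ranking, C-alpha contact-fraction
    selection), plurality-consensus motif extraction from substitution
    mutant libraries, and geometric descriptor analysis of molecular
    dynamics trajectories (centre-of-mass distance, inter-chain angle,
    binding-state classification, quality-threshold conformational
    clustering, residue-pair contact lifetimes). Seeded synthetic-structure
    generators with planted ground truth stand in for external docking and
    simulation engines so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    cluster,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
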